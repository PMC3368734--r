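test_that("single-exon transcripts are removed with a notice", {
    fx <- tarFixture()
    expect_message(multi <- filterMultiExon(fx$rec), "removed 3")
    expect_length(multi, 9L)
    expect_identical(txId(multi), setdiff(txId(fx$rec),
                                          c("s1", "s2", "s3")))
    empty <- mkTxSet(list(x = mkTx(1, 100)), geneId = "g")
    expect_message(none <- filterMultiExon(empty), "removed 1")
    expect_length(none, 0L)
})

test_that("pairwise overlap needs one shared splice site on one strand", {
    fx <- tarFixture()
    m <- suppressMessages(filterMultiExon(fx$rec))
    expect_true(transcriptsOverlap(m["A1"], m["A1"]))   # identical
    expect_true(transcriptsOverlap(m["A1"], m["A2"]))   # shared boundary
    expect_false(transcriptsOverlap(m["A1"], m["A3"]))  # chain ends only
    expect_false(transcriptsOverlap(m["B1"], m["B2"]))  # strand decoys
    expect_false(transcriptsOverlap(m["C1"], m["A1"]))
})

test_that("the fixture clusters, classifies and tallies exactly", {
    fx <- tarFixture()
    m <- suppressMessages(filterMultiExon(fx$rec))
    tars <- clusterTars(m)
    expect_equal(nrow(tarInfo(tars)), 6L)      # A, B1, B2, C, D, E+F
    memb <- tarMembership(tars)
    expect_equal(length(unique(memb[c("A1", "A2", "A3")])), 1L)
    expect_false(memb[["B1"]] == memb[["B2"]])
    expect_equal(length(unique(memb[c("E1", "F1")])), 1L)
    # every transcript lands in exactly one TAR and counts add up
    expect_length(memb, 9L)
    expect_equal(sum(tarInfo(tars)$nMembers), 9L)

    tars <- classifyTarNovelty(tars, fx$ann)
    info <- tarInfo(tars)
    novOf <- function(tx) info$novelty[memb[[tx]]]
    expect_equal(novOf("E1"), "known")
    expect_equal(novOf("F1"), "known")
    expect_equal(novOf("C1"), "novel")   # intergenic plant
    expect_equal(novOf("D1"), "novel")   # span overlap is not enough
    expect_equal(novOf("A1"), "novel")
    expect_equal(sum(info$novelty == "novel"), 5L)

    cls <- classifyInternalExons(tars, fx$ann)
    # the known TAR has two internal exons, both intronic relative to the
    # annotation: E1's 20200-20300 and F1's 20500-20550 -> no_overlap
    expect_equal(unname(cls$tally),
                 c(annotated = 0L, one_end_shared = 0L,
                   overlap_no_shared_end = 0L, no_overlap = 2L),
                 ignore_attr = TRUE)
    expect_error(classifyInternalExons(tars, fx$ann,
        tarIds = info$tar_id[info$novelty == "novel"][1]),
        "known")
})

test_that("exon classes cover the four categories exclusively", {
    ann <- mkTxSet(list(K = mkTx(c(100, 200, 900, 2000),
                                 c(150, 300, 1000, 2100))), geneId = "g")
    rec <- mkTxSet(list(
        R1 = mkTx(c(100, 200, 900, 2000), c(150, 300, 1000, 2100)),
        R2 = mkTx(c(100, 200, 900, 2000), c(150, 350, 1000, 2100)),
        R3 = mkTx(c(100, 250, 900, 2000), c(150, 280, 1000, 2100)),
        R4 = mkTx(c(100, 1200, 2000), c(150, 1300, 2100))))
    tars <- classifyTarNovelty(clusterTars(rec), ann)
    cls <- classifyInternalExons(tars, ann)
    df <- as.data.frame(cls$perExon)
    catOf <- function(tx, s) df$category[df$transcript_id == tx &
                                         df$start == s]
    expect_equal(catOf("R1", 200), "annotated")
    expect_equal(catOf("R2", 200), "one_end_shared")        # start shared
    expect_equal(catOf("R3", 250), "overlap_no_shared_end") # nested
    expect_equal(catOf("R4", 1200), "no_overlap")           # intronic
    expect_equal(sum(cls$tally), nrow(df))   # exhaustive and exclusive
    expect_equal(unname(rowSums(cls$perTar)), nrow(df))
})

test_that("components agree with a transitive-closure oracle", {
    withr::with_seed(29, for (rep in 1:5) {
        n <- sample(20:50, 1)
        # random transcripts drawing boundaries from a small pool so that
        # shared splice sites are common
        pool <- seq(1000, 20000, by = 200)
        txs <- lapply(seq_len(n), function(i) {
            k <- sample(2:4, 1)
            b <- sort(sample(pool, 2 * k))
            mkTx(b[seq(1, 2 * k, 2)] + 1, b[seq(2, 2 * k, 2)],
                 strand = sample(c("+", "-"), 1))
        })
        names(txs) <- paste0("t", seq_len(n))
        ts <- mkTxSet(txs, geneId = names(txs))
        tars <- clusterTars(ts)
        memb <- tarMembership(tars)
        # oracle: pairwise overlap matrix -> boolean transitive closure
        keys <- placentome:::.boundaryKeys(ts)
        adj <- matrix(FALSE, n, n)
        for (i in seq_len(n)) for (j in seq_len(n))
            adj[i, j] <- any(keys[[i]] %in% keys[[j]])
        # key-based adjacency equals the public pairwise predicate
        ij <- cbind(sample(n, 8, TRUE), sample(n, 8, TRUE))
        for (r in seq_len(nrow(ij)))
            expect_equal(adj[ij[r, 1], ij[r, 2]],
                         transcriptsOverlap(ts[ij[r, 1]], ts[ij[r, 2]]))
        oracle <- closureComponents(adj)
        expect_equal(length(unique(memb)), length(unique(oracle)))
        # same partition: equal membership iff equal oracle component
        expect_true(all(outer(memb, memb, "==") ==
                        outer(oracle, oracle, "==")))
    })
})

test_that("novel-TAR expression reuses the FPKM machinery and flags", {
    fx <- tarFixture()
    m <- suppressMessages(filterMultiExon(fx$rec))
    tars <- classifyTarNovelty(clusterTars(m), fx$ann)
    info <- tarInfo(tars)
    novel <- info$tar_id[info$novelty == "novel"]
    tissues <- c("plac", paste0("b", 1:3))
    counts <- matrix(5L, length(novel), 4,
                     dimnames = list(novel, tissues))
    counts[1, ] <- c(50L, 0L, 0L, 0L)     # specific-like
    counts[2, ] <- c(400L, 8L, 8L, 8L)    # enriched-like
    counts[3, ] <- c(16L, 8L, 8L, 8L)     # 2-fold: neither
    out <- novelTarExpression(tars, counts,
        librarySize = rep(1e6, 4), target = "plac",
        background = paste0("b", 1:3))
    expect_true(out$specific$specific[1])
    expect_true(out$enriched$enriched[2])
    expect_false(out$enriched$enriched[3])
    expect_false(out$specific$specific[3])
})

test_that("planted cohort novelty is recovered perfectly", {
    cfg <- CohortConfig(nGenes = 60L, nCassetteExons = 10L,
                        nEnrichedPerTarget = 2L, nEnrichedShared = 1L,
                        nSpecificPerTarget = 1L, seed = 27L)
    co <- simulateCohort(cfg, nNovelTars = 4L, nNovelExons = 4L,
                         nNoise = 6L)
    m <- suppressMessages(filterMultiExon(co$reconstructed))
    tars <- classifyTarNovelty(clusterTars(m), co$annotation)
    memb <- tarMembership(tars)
    nov <- tarInfo(tars)$novelty
    # every planted intergenic transcript sits in a novel TAR, every
    # jittered copy in a known one
    expect_true(all(nov[memb[co$truth@novelTars]] == "novel"))
    expect_true(all(nov[memb[co$truth@knownCopies]] == "known"))
    expect_equal(sum(nov == "novel"), length(co$truth@novelTars))
    # planted novel internal exons come out as no_overlap
    cls <- classifyInternalExons(tars, co$annotation)
    df <- as.data.frame(cls$perExon)
    for (i in seq_along(co$truth@novelExons)) {
        ne <- co$truth@novelExons[i]
        hit <- df[df$start == start(ne) & df$end == end(ne) &
                  df$chrom == as.character(seqnames(ne)), ]
        expect_gt(nrow(hit), 0)
        expect_true(all(hit$category == "no_overlap"))
    }
    expect_equal(unname(cls$tally[c("one_end_shared",
                                    "overlap_no_shared_end")]),
                 c(0L, 0L))
})
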