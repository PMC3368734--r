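test_that("FPKM matches the scalar formula, including its invariances", {
    expect_equal(computeFPKM(matrix(1000, 1, 1,
                                    dimnames = list("g", "t")),
                             librarySize = 5e7, unionLength = 2000)[1, 1],
                 10)
    withr::with_seed(1, {
        cts <- matrix(rpois(60, 50), 10, 6,
                      dimnames = list(paste0("g", 1:10), paste0("t", 1:6)))
        ls <- sample(1e6:5e7, 6)
        ul <- sample(300:5000, 10)
        fp <- computeFPKM(cts, librarySize = ls, unionLength = ul)
        for (i in 1:10) for (j in 1:6)
            expect_equal(fp[i, j],
                         cts[i, j] / (ul[i] / 1e3) / (ls[j] / 1e6),
                         tolerance = 1e-12)
        # joint doubling of counts and library size leaves FPKM unchanged
        expect_equal(computeFPKM(2 * cts, librarySize = 2 * ls,
                                 unionLength = ul), fp,
                     tolerance = 1e-12)
        expect_true(all(fp[cts == 0] == 0))
    })
    expect_error(computeFPKM(matrix(1, 2, 2,
        dimnames = list(c("a", "b"), c("x", "y"))),
        librarySize = 1e6, unionLength = c(100, 100)), "per tissue")
    expect_error(computeFPKM(matrix(1, 1, 1, dimnames = list("a", "x")),
        librarySize = 0, unionLength = 100), ">= 1")
})

test_that("detection counting is strict and shape-stable", {
    fp <- matrix(c(0.5, 2, 3, 0, 0, 0), 3, 2,
                 dimnames = list(paste0("g", 1:3), c("a", "b")))
    ds <- detectionSummary(fp, thresholds = c(0, 1))
    expect_equal(ds$nDetected[ds$tissue == "a" & ds$threshold == 1], 2)
    expect_equal(ds$nDetected[ds$tissue == "b" & ds$threshold == 0], 0)
    expect_equal(nrow(detectionSummary(fp, thresholds = numeric(0))), 0)
})

test_that("enrichment calling applies the strict 4-fold rule", {
    cts <- rbind(gHi = c(80, 15, 15), gLow = c(9, 1, 1),
                 gEdge = c(40, 10, 10), gInf = c(50, 0, 0))
    colnames(cts) <- c("plac", "b1", "b2")
    te <- computeFPKM(TissueExpression(cts, librarySize = rep(1e6, 3),
                                       unionLength = rep(1000, 4)))
    enr <- callTissueEnriched(te, "plac", c("b1", "b2"))
    got <- setNames(enr$enriched, enr$gene_id)
    expect_true(got[["gHi"]])      # fold 5.33
    expect_false(got[["gEdge"]])   # fold exactly 4: excluded
    expect_true(got[["gInf"]])     # zero background: fold = Inf
    expect_equal(unname(enr$fold[enr$gene_id == "gInf"]), Inf)
    # a gene with target FPKM 0.9 fails min FPKM despite a 9-fold difference
    m2 <- rbind(g = c(9, 1, 1))
    colnames(m2) <- c("plac", "b1", "b2")
    lo <- callTissueEnriched(computeFPKM(TissueExpression(m2,
        librarySize = rep(1e7, 3), unionLength = 1000)),
        "plac", c("b1", "b2"))
    expect_false(lo$enriched[1])
    expect_error(callTissueEnriched(te, "nope", c("b1", "b2")), "unknown")
    expect_error(callTissueEnriched(te, "plac", character(0)), "non-empty")
    # raising the fold threshold can never grow the enriched set
    e6 <- callTissueEnriched(te, "plac", c("b1", "b2"), minFold = 6)
    expect_true(all(enr$enriched[e6$enriched]))
})

test_that("specificity is presence/absence with a separate FPKM flag", {
    cts <- rbind(gSpec = c(5, 0, 0),     # specific, FPKM 0.5
                 gFaint = c(2, 0, 0),    # specific but below 0.3 filter
                 gLeak = c(50, 1, 0))    # one background read: not specific
    colnames(cts) <- c("plac", "b1", "b2")
    te <- TissueExpression(cts, librarySize = rep(1e7, 3),
                           unionLength = rep(1000, 3))
    sp <- callTissueSpecific(te, "plac", c("b1", "b2"))
    got <- setNames(sp$specific, sp$gene_id)
    flt <- setNames(sp$passesFpkmFilter, sp$gene_id)
    expect_true(got[["gSpec"]]);  expect_true(flt[["gSpec"]])
    expect_true(got[["gFaint"]]); expect_false(flt[["gFaint"]])
    expect_false(got[["gLeak"]])
})

test_that("divergent-gene ranking follows CV with deterministic ties", {
    fp <- rbind(flat = rep(10, 9),
                spiky = c(10, 10, 10, 30, 10, 10, 10, 10, 10),
                rare = c(6, 6, 6, 6, 6, 6, 6, 0, 0))
    colnames(fp) <- paste0("t", 1:9)
    div <- suppressMessages(selectDivergentGenes(fp, minFpkm = 5,
                                                 minTissues = 8, topK = 10))
    expect_false("rare" %in% div$gene_id)      # expressed in only 7 tissues
    expect_equal(div$gene_id[1], "spiky")
    expect_equal(div$cv[div$gene_id == "flat"], 0)
    # population-sd CV of (10,10,10,30) is 0.577
    fp4 <- rbind(x = c(10, 10, 10, 30))
    colnames(fp4) <- paste0("t", 1:4)
    d4 <- suppressMessages(selectDivergentGenes(fp4, minFpkm = 5,
                                                minTissues = 4, topK = 1))
    expect_equal(d4$cv, sqrt(75) / 15, tolerance = 1e-12)
    expect_message(selectDivergentGenes(fp, minFpkm = 5, minTissues = 8,
                                        topK = 10), "fewer than topK")
})

test_that("profile clustering reproduces a naive UPGMA oracle", {
    # identical profiles sit at distance 0, anti-correlated at 2
    m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
    d <- 1 - cor(t(m))
    expect_equal(d["a", "b"], 0, tolerance = 1e-12)
    expect_equal(d["a", "c"], 2, tolerance = 1e-12)
    withr::with_seed(11, for (rep in 1:10) {
        n <- sample(4:5, 1)
        m <- matrix(rnorm(n * 6), n, 6,
                    dimnames = list(paste0("g", 1:n), paste0("t", 1:6)))
        cl <- clusterProfiles(m)
        orc <- upgmaOracle(1 - cor(t(m)))
        expect_equal(cl$geneDendro$height, orc$heights, tolerance = 1e-9)
        expect_identical(hclustMerges(cl$geneDendro), orc$merges)
    })
    expect_error(clusterProfiles(matrix(1, 3, 3)), "zero variance")
})
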