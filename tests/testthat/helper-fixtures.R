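# small builders and independent oracles shared across test files

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
    library(S4Vectors)
})

# one transcript from start/end vectors
mkTx <- function(starts, ends, strand = "+", chrom = "chr1") {
    GRanges(chrom, IRanges(starts, ends), strand)
}

# a TranscriptSet from a named list of GRanges
mkTxSet <- function(txList, geneId = names(txList)) {
    TranscriptSet(GRangesList(txList, compress = TRUE), geneId = geneId)
}

# brute-force per-base exon-union length (bitmap oracle)
unionLengthOracle <- function(grl) {
    flat <- unlist(grl, use.names = FALSE)
    covered <- unique(unlist(mapply(seq, start(flat), end(flat),
                                    SIMPLIFY = FALSE)))
    length(covered)
}

# naive UPGMA: recompute average inter-cluster distances from the raw
# matrix at every step (independent of stats::hclust internals)
upgmaOracle <- function(d) {
    d <- as.matrix(d)
    n <- nrow(d)
    clusters <- as.list(seq_len(n))
    heights <- numeric(0)
    merges <- list()
    while (length(clusters) > 1) {
        best <- c(NA, NA); bestD <- Inf
        for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
            if (i >= j) next
            dd <- mean(d[clusters[[i]], clusters[[j]], drop = FALSE])
            if (dd < bestD) { bestD <- dd; best <- c(i, j) }
        }
        heights <- c(heights, bestD)
        merges <- c(merges, list(sort(c(clusters[[best[1]]],
                                        clusters[[best[2]]]))))
        clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
        clusters[[best[2]]] <- NULL
    }
    list(heights = heights, merges = merges)
}

# cluster partitions of an hclust at each merge step, as sorted leaf sets
hclustMerges <- function(hc) {
    n <- length(hc$order)
    sets <- vector("list", n - 1)
    for (m in seq_len(n - 1)) {
        grab <- function(i) {
            if (i < 0) return(-i)
            sort(sets[[i]])
        }
        sets[[m]] <- sort(c(grab(hc$merge[m, 1]), grab(hc$merge[m, 2])))
    }
    sets
}

# boolean transitive closure of an adjacency matrix (Floyd-Warshall style)
closureComponents <- function(adj) {
    n <- nrow(adj)
    reach <- adj | diag(TRUE, n)
    for (k in seq_len(n))
        reach <- reach | (reach[, k] %o% reach[k, ])
    comp <- integer(n); cur <- 0L
    for (i in seq_len(n)) {
        if (comp[i] == 0L) {
            cur <- cur + 1L
            comp[reach[i, ]] <- cur
        }
    }
    comp
}

# hypergeometric tail probabilities from binomial coefficients only
# (independent of dhyper/phyper and of the package implementation)
hyperOracle <- function(a, b, cc, d, alternative) {
    m <- a + cc; n <- b + d; k <- a + b
    supp <- max(0, k - n):min(k, m)
    logp <- lchoose(m, supp) + lchoose(n, k - supp) - lchoose(m + n, k)
    pr <- exp(logp)
    pObs <- pr[match(a, supp)]
    switch(alternative,
        greater = sum(pr[supp >= a]),
        less = sum(pr[supp <= a]),
        two.sided = sum(pr[pr <= pObs * (1 + 1e-7)]))
}

# junction triples for a two-condition SpliceEventSet, I = k exactly
mkEventSet <- function(k1, n1, k2, n2) {
    ne <- length(k1)
    exon <- GRanges("chrT", IRanges(seq_len(ne) * 1000L, width = 100L), "+",
                    gene_id = sprintf("g%05d", seq_len(ne)))
    names(exon) <- sprintf("e%05d", seq_len(ne))
    m <- function(a, b) matrix(c(a, b), ne, 2,
                               dimnames = list(names(exon),
                                               c("cond1", "cond2")))
    SpliceEventSet(exon, ujc = m(k1, k2), djc = m(k1, k2),
                   sjc = m(n1 - k1, n2 - k2))
}

# hand-built reconstructed-transcript fixture, 12 records:
#   A1, A2, A3: chain on chr1:+ (A1-A2 and A2-A3 share a splice site,
#               A1 and A3 share none) -> one TAR
#   B1, B2: identical structure but opposite strands -> two TARs
#   C1: intergenic multi-exon plant sharing nothing -> novel TAR
#   D1: span-overlaps the annotation without sharing a boundary -> novel
#   E1: matches an annotated transcript with jittered termini -> known
#   F1: known transcript plus a novel intronic internal exon -> known
#   s1, s2, s3: single-exon noise
tarFixture <- function() {
    rec <- mkTxSet(list(
        A1 = mkTx(c(1000, 2000), c(1500, 2500)),
        A2 = mkTx(c(1200, 2000, 3000), c(1500, 2500, 3200)),
        A3 = mkTx(c(2501, 3000), c(2700, 3200)),
        B1 = mkTx(c(9000, 9500), c(9200, 9700)),
        B2 = mkTx(c(9000, 9500), c(9200, 9700), strand = "-"),
        C1 = mkTx(c(50000, 50400), c(50100, 50500)),
        D1 = mkTx(c(20010, 20810), c(20190, 20900)),
        E1 = mkTx(c(19990, 20200, 20800), c(20100, 20300, 20950)),
        F1 = mkTx(c(20000, 20500, 20800), c(20100, 20550, 20900)),
        s1 = mkTx(100, 300), s2 = mkTx(60000, 60400),
        s3 = mkTx(70000, 70100, strand = "-")))
    ann <- mkTxSet(list(
        K1 = mkTx(c(20000, 20800), c(20100, 20900))),
        geneId = "gK")
    list(rec = rec, ann = ann)
}

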