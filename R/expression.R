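#' @include AllClasses.R AllGenerics.R
NULL

#' FPKM from fragment counts
#'
#' Fragments Per Kilobase of exon-union length per Million mapped fragments:
#' \deqn{FPKM_{g,t} = \frac{C_{g,t}}{(L_g/10^3)\,(N_t/10^6)}}
#' with \eqn{C} the fragment count of gene g in tissue t, \eqn{L} the gene's
#' exon-union length in bp and \eqn{N} the tissue's total mapped fragments.
#' Counting against the exon union (rather than per isoform) avoids the
#' ambiguity of assigning reads across isoforms.
#'
#' @param x a counts matrix (genes x tissues) or a
#'   \code{\link{TissueExpression}}.
#' @param librarySize per-tissue total mapped fragments (matrix method).
#' @param unionLength per-gene exon-union length in bp (matrix method).
#' @param ... unused.
#' @return matrix method: the FPKM matrix; \code{TissueExpression} method:
#'   the object with an \code{fpkm} assay added.
#' @examples
#' computeFPKM(matrix(1000, 1, 1, dimnames = list("g", "t")),
#'             librarySize = 5e7, unionLength = 2000)  # 10
#' @export
setMethod("computeFPKM", "matrix", function(x, librarySize, unionLength, ...) {
    if (length(librarySize) != ncol(x))
        stop("librarySize must have one entry per tissue column")
    if (length(unionLength) != nrow(x))
        stop("unionLength must have one entry per gene row")
    if (any(librarySize < 1))
        stop("library sizes must be >= 1")
    if (any(unionLength < 1))
        stop("union lengths must be >= 1 bp")
    x / (as.numeric(unionLength) / 1e3) /
        rep(as.numeric(librarySize) / 1e6, each = nrow(x))
})

#' @rdname computeFPKM-matrix-method
#' @export
setMethod("computeFPKM", "TissueExpression", function(x, ...) {
    fp <- computeFPKM(assay(x, "counts"),
                      librarySize = colData(x)$librarySize,
                      unionLength = rowData(x)$unionLength)
    SummarizedExperiment::assay(x, "fpkm") <- fp
    validObject(x)
    x
})

#' Count genes detected above FPKM cutoffs
#'
#' Detection is strict (FPKM > cutoff), so a cutoff of 0 counts genes with
#' any signal at all.
#'
#' @param fpkm FPKM matrix or a \code{TissueExpression} with an fpkm assay
#' @param thresholds numeric vector of FPKM cutoffs (>= 0)
#' @return data.frame with columns \code{tissue}, \code{threshold},
#'   \code{nDetected}
#' @export
detectionSummary <- function(fpkm, thresholds = c(0, 1, 5)) {
    if (is(fpkm, "TissueExpression"))
        fpkm <- fpkm(fpkm)
    stopifnot(all(thresholds >= 0))
    if (!length(thresholds))
        return(data.frame(tissue = character(0), threshold = numeric(0),
                          nDetected = integer(0)))
    do.call(rbind, lapply(thresholds, function(th)
        data.frame(tissue = colnames(fpkm), threshold = th,
                   nDetected = colSums(fpkm > th), row.names = NULL)))
}

.checkTissues <- function(x, target, background) {
    all <- colnames(x)
    bad <- setdiff(c(target, background), all)
    if (length(bad))
        stop("unknown tissue(s): ", paste(bad, collapse = ", "))
    if (target %in% background)
        stop("target tissue must not be in the background set")
    if (!length(background))
        stop("background set must be non-empty")
}

#' Call tissue-enriched genes
#'
#' A gene is enriched in the target tissue when its target FPKM is at least
#' \code{minFpkm} and exceeds the arithmetic mean of its background FPKM by
#' strictly more than \code{minFold}. A gene at exactly the fold threshold
#' is not called. When the background mean is zero and the target is
#' expressed, the fold is reported as \code{Inf} (presence/absence
#' semantics, no pseudocount), so such genes pass any finite fold threshold.
#'
#' @param x a \code{\link{TissueExpression}} with an fpkm assay (run
#'   \code{\link{computeFPKM}} first)
#' @param target target tissue name
#' @param background character vector of background tissue names
#' @param minFpkm minimum target FPKM (default 1)
#' @param minFold fold threshold, strict (default 4)
#' @return \code{DataFrame}: \code{gene_id}, \code{targetTissue},
#'   \code{targetFpkm}, \code{backgroundMean}, \code{fold}, \code{enriched}
#' @export
callTissueEnriched <- function(x, target, background, minFpkm = 1,
                               minFold = 4) {
    .checkTissues(x, target, background)
    fp <- fpkm(x)
    tv <- fp[, target]
    bg <- rowMeans(fp[, background, drop = FALSE])
    fold <- ifelse(bg > 0, tv / bg, ifelse(tv > 0, Inf, NA_real_))
    DataFrame(gene_id = rownames(fp), targetTissue = target,
              targetFpkm = tv, backgroundMean = bg, fold = fold,
              enriched = tv >= minFpkm & !is.na(fold) & fold > minFold,
              row.names = NULL)
}

#' Call tissue-specific genes
#'
#' Specificity is a presence/absence call on raw fragment counts: a gene is
#' specific to the target tissue when not a single fragment was observed in
#' any background tissue while the target has at least one. A second flag
#' (\code{passesFpkmFilter}) marks specific genes whose target FPKM strictly
#' exceeds \code{minTargetFpkm}, removing genes with universally low
#' expression that happened to be sampled only in the target.
#'
#' @inheritParams callTissueEnriched
#' @param minTargetFpkm FPKM filter for the second-stage flag (default 0.3)
#' @return \code{DataFrame}: \code{gene_id}, \code{targetTissue},
#'   \code{targetCount}, \code{targetFpkm}, \code{specific},
#'   \code{passesFpkmFilter}
#' @export
callTissueSpecific <- function(x, target, background, minTargetFpkm = 0.3) {
    .checkTissues(x, target, background)
    cts <- assay(x, "counts")
    fp <- if ("fpkm" %in% assayNames(x)) fpkm(x) else
        computeFPKM(cts, colData(x)$librarySize, rowData(x)$unionLength)
    bgZero <- rowSums(cts[, background, drop = FALSE] > 0) == 0
    spec <- bgZero & cts[, target] > 0
    DataFrame(gene_id = rownames(cts), targetTissue = target,
              targetCount = cts[, target], targetFpkm = fp[, target],
              specific = spec,
              passesFpkmFilter = spec & fp[, target] > minTargetFpkm,
              row.names = NULL)
}

#' Select the most divergent genes by coefficient of variation
#'
#' Keeps genes expressed above \code{minFpkm} (strict) in at least
#' \code{minTissues} tissues, ranks them by descending coefficient of
#' variation of FPKM across all tissues, and returns the top \code{topK}.
#' CV uses the population standard deviation by default (\code{popSd});
#' ties are broken by gene id for reproducibility.
#'
#' @param fpkm FPKM matrix or \code{TissueExpression} with an fpkm assay
#' @param minFpkm expression cutoff, strict (default 5)
#' @param minTissues minimum number of tissues above the cutoff (default 8)
#' @param topK how many genes to return (default 1000); if fewer survive
#'   the filter, all survivors are returned with a notice
#' @param popSd divide by n (default) rather than n - 1
#' @return data.frame with \code{gene_id}, \code{cv}, \code{nExpressed},
#'   ranked by descending CV
#' @export
selectDivergentGenes <- function(fpkm, minFpkm = 5, minTissues = 8,
                                 topK = 1000, popSd = TRUE) {
    stopifnot(topK >= 1)
    if (is(fpkm, "TissueExpression"))
        fpkm <- fpkm(fpkm)
    nExpr <- rowSums(fpkm > minFpkm)
    keep <- nExpr >= minTissues
    m <- fpkm[keep, , drop = FALSE]
    mu <- rowMeans(m)
    sdv <- sqrt(rowMeans((m - mu)^2))
    if (!popSd)
        sdv <- sdv * sqrt(ncol(m) / (ncol(m) - 1))
    cv <- ifelse(mu > 0, sdv / mu, 0)
    ord <- order(-cv, rownames(m))
    res <- data.frame(gene_id = rownames(m)[ord], cv = cv[ord],
                      nExpressed = nExpr[keep][ord], row.names = NULL)
    if (nrow(res) < topK)
        message(nrow(res), " genes survive the expression filter ",
                "(fewer than topK = ", topK, "); returning all")
    utils::head(res, topK)
}

#' Average-linkage clustering of expression profiles
#'
#' Hierarchically clusters genes and tissues with unweighted average linkage
#' on the 1 - Pearson correlation distance. Rows and columns without
#' variance are dropped with a notice (correlation is undefined for them).
#' The returned display matrix is the per-gene z-score across tissues;
#' scaling is for display only and plays no part in the distances.
#'
#' @param m FPKM (sub)matrix, genes x tissues, at least 2 x 2
#' @return list with \code{geneDendro} and \code{tissueDendro}
#'   (\code{hclust} objects) and \code{matrix}, the z-scored matrix with
#'   rows and columns in dendrogram order
#' @export
clusterProfiles <- function(m) {
    m <- as.matrix(m)
    rowVar <- apply(m, 1, stats::var)
    if (all(rowVar == 0))
        stop("all rows have zero variance; nothing to cluster")
    if (any(rowVar == 0)) {
        message("dropping ", sum(rowVar == 0), " zero-variance row(s)")
        m <- m[rowVar > 0, , drop = FALSE]
    }
    colVar <- apply(m, 2, stats::var)
    if (any(colVar == 0)) {
        message("dropping ", sum(colVar == 0), " zero-variance column(s)")
        m <- m[, colVar > 0, drop = FALSE]
    }
    if (nrow(m) < 2 || ncol(m) < 2)
        stop("need at least 2 informative rows and columns")
    geneD <- stats::hclust(as.dist(1 - cor(t(m))), method = "average")
    tisD <- stats::hclust(as.dist(1 - cor(m)), method = "average")
    z <- t(scale(t(m)))
    list(geneDendro = geneD, tissueDendro = tisD,
         matrix = z[geneD$order, tisD$order, drop = FALSE])
}
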