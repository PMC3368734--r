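#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<- Rle
#' @importFrom IRanges IRanges IRangesList CharacterList IntegerList
#'   start<- end<-
#' @importFrom GenomicRanges GRanges GRangesList seqnames strand start end
#'   width
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames
#'   rowData colData rowRanges
NULL

setClassUnion("integerOrNumeric", c("integer", "numeric"))

#' TranscriptSet: strand-aware exon structures for a set of transcripts
#'
#' A \code{TranscriptSet} holds one \code{GRanges} of exons per transcript
#' (a \code{GRangesList} named by transcript id) together with the parallel
#' gene-id assignment. Exons are stored 1-based closed (the
#' \code{GenomicRanges} convention); GTF and BED12 conventions are converted
#' at the I/O edge by \code{\link{readAnnotation}} / \code{\link{writeAnnotation}}.
#'
#' Validity requires, per transcript: at least one exon; a single chromosome
#' and a single strand (\code{+} or \code{-}; strandless records are
#' rejected); exons sorted by start, pairwise non-overlapping and separated
#' by at least one intronic base.
#'
#' @slot exons \code{GRangesList}, one element per transcript, names are
#'   transcript ids.
#' @slot geneId character vector parallel to \code{exons}.
#' @export
setClass("TranscriptSet",
    representation(exons = "GRangesList", geneId = "character"))

setValidity("TranscriptSet", function(object) {
    ex <- object@exons
    if (length(ex) != length(object@geneId))
        return("geneId must be parallel to exons")
    if (length(ex) == 0L)
        return(TRUE)
    if (is.null(names(ex)) || anyDuplicated(names(ex)))
        return("transcripts must carry unique names (transcript ids)")
    n <- S4Vectors::elementNROWS(ex)
    if (any(n < 1L))
        return("every transcript needs at least one exon")
    flat <- unlist(ex, use.names = FALSE)
    grp <- rep(seq_along(ex), n)
    m <- length(flat)
    same <- grp[-1L] == grp[-m]
    chr <- as.character(seqnames(flat))
    if (any(same & chr[-1L] != chr[-m]))
        return("all exons of a transcript must share one chromosome")
    str <- as.character(strand(flat))
    if (any(!str %in% c("+", "-")))
        return("strandless exons are not allowed (strand must be + or -)")
    if (any(same & str[-1L] != str[-m]))
        return("all exons of a transcript must share one strand")
    # sortedness and >= 1 bp gap between consecutive exons, per transcript
    if (any(same & (start(flat)[-1L] - end(flat)[-m] < 2L)))
        return(paste0("exons within a transcript must be sorted, ",
                      "non-overlapping and non-adjacent (gap >= 1 bp)"))
    TRUE
})

#' Construct a TranscriptSet
#'
#' @param exons a named \code{GRangesList} (one element per transcript) or a
#'   single \code{GRanges} that is then treated as a one-transcript set.
#' @param geneId character vector of gene ids, parallel to \code{exons};
#'   defaults to the transcript ids.
#' @return a \code{TranscriptSet}
#' @examples
#' ex <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 201), c(100, 300)), "+")
#' ts <- TranscriptSet(GenomicRanges::GRangesList(tx1 = ex), geneId = "g1")
#' @export
TranscriptSet <- function(exons, geneId = names(exons)) {
    if (is(exons, "GRanges"))
        exons <- GRangesList(tx1 = exons)
    if (is.list(exons))
        exons <- GRangesList(exons, compress = TRUE)
    if (!is(exons, "GRangesList"))
        stop("exons must be a GRangesList")
    nms <- names(exons)
    n <- S4Vectors::elementNROWS(exons)
    flat <- unlist(exons, use.names = FALSE)
    mcols(flat) <- NULL
    grp <- rep(seq_along(exons), n)
    flat <- flat[order(grp, start(flat))]
    exons <- IRanges::relist(flat,
        IRanges::PartitioningByEnd(cumsum(n), names = nms))
    if (is.null(geneId))
        geneId <- names(exons)
    new("TranscriptSet", exons = exons, geneId = as.character(geneId))
}

#' TissueExpression: gene-level fragment counts across a tissue panel
#'
#' Extends \code{SummarizedExperiment}. The \code{counts} assay holds
#' non-negative integer fragment counts (genes x tissues), \code{colData}
#' carries \code{librarySize} (total mapped fragments per tissue) and
#' \code{rowData} carries \code{unionLength} (exon-union length in bp).
#' \code{\link{computeFPKM}} adds the derived \code{fpkm} assay.
#'
#' @export
setClass("TissueExpression", contains = "SummarizedExperiment")

setValidity("TissueExpression", function(object) {
    if (!"counts" %in% assayNames(object))
        return("a 'counts' assay is required")
    cts <- assay(object, "counts")
    if (any(cts < 0) || any(cts != round(cts)))
        return("counts must be non-negative integers")
    if (!"librarySize" %in% colnames(colData(object)))
        return("colData must carry librarySize")
    if (!"unionLength" %in% colnames(rowData(object)))
        return("rowData must carry unionLength")
    if (any(rowData(object)$unionLength < 1))
        return("unionLength must be >= 1 bp")
    if ("fpkm" %in% assayNames(object)) {
        fp <- assay(object, "fpkm")
        if (any((fp == 0) != (cts == 0)))
            return("fpkm must be zero exactly where counts is zero")
    }
    TRUE
})

#' Construct a TissueExpression object
#'
#' @param counts genes x tissues matrix of fragment counts (dimnames required).
#' @param librarySize per-tissue total mapped fragments. By default the
#'   column sums of \code{counts} (the synthetic-cohort convention); real
#'   libraries pass the mapped-fragment totals explicitly.
#' @param unionLength per-gene exon-union length in bp, named by gene.
#' @return a \code{TissueExpression}
#' @export
TissueExpression <- function(counts, librarySize = colSums(counts), unionLength) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts needs gene rownames and tissue colnames")
    if (!is.null(names(unionLength)))
        unionLength <- unionLength[rownames(counts)]
    if (length(unionLength) != nrow(counts) || anyNA(unionLength))
        stop("unionLength must cover every gene in counts")
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(unionLength = as.numeric(unionLength),
                            row.names = rownames(counts)),
        colData = DataFrame(librarySize = as.numeric(librarySize),
                            row.names = colnames(counts)))
    new("TissueExpression", se)
}

#' SpliceEventSet: cassette exons with per-tissue junction counts
#'
#' Extends \code{RangedSummarizedExperiment}. \code{rowRanges} is the cassette
#' exon of each event (with \code{gene_id} in \code{mcols}); the three assays
#' \code{ujc}, \code{djc}, \code{sjc} are events x tissues matrices of
#' upstream-junction, downstream-junction and skipping-junction read counts.
#'
#' @export
setClass("SpliceEventSet", contains = "RangedSummarizedExperiment")

setValidity("SpliceEventSet", function(object) {
    need <- c("ujc", "djc", "sjc")
    if (!all(need %in% assayNames(object)))
        return("assays ujc, djc and sjc are required")
    for (nm in need) {
        a <- assay(object, nm)
        if (any(a < 0) || any(a != round(a)))
            return(sprintf("assay '%s' must hold non-negative integer counts", nm))
    }
    if (!"gene_id" %in% colnames(mcols(rowRanges(object))))
        return("rowRanges must carry gene_id")
    TRUE
})

#' Construct a SpliceEventSet
#'
#' @param exon \code{GRanges} of cassette exons (one per event) with a
#'   \code{gene_id} metadata column; names are event ids.
#' @param ujc,djc,sjc events x tissues integer count matrices with matching
#'   dimnames.
#' @return a \code{SpliceEventSet}
#' @export
SpliceEventSet <- function(exon, ujc, djc, sjc) {
    ujc <- as.matrix(ujc); djc <- as.matrix(djc); sjc <- as.matrix(sjc)
    stopifnot(identical(dim(ujc), dim(djc)), identical(dim(ujc), dim(sjc)))
    if (is.null(names(exon)))
        names(exon) <- rownames(ujc)
    se <- SummarizedExperiment(
        assays = list(ujc = ujc, djc = djc, sjc = sjc),
        rowRanges = exon)
    new("SpliceEventSet", se)
}

#' TarSet: transcriptional active regions from reconstructed transcripts
#'
#' The result of \code{\link{clusterTars}}: the clustered multi-exon
#' transcripts, the TAR membership of each transcript, and a per-TAR summary
#' table (span, strand, member count and, after
#' \code{\link{classifyTarNovelty}}, the novelty call).
#'
#' @slot transcripts the clustered \code{TranscriptSet}.
#' @slot membership integer TAR index per transcript.
#' @slot tarInfo \code{DataFrame} with one row per TAR: \code{tar_id},
#'   \code{chrom}, \code{start}, \code{end}, \code{strand}, \code{nMembers},
#'   \code{novelty} (\code{"known"}, \code{"novel"} or \code{NA} before
#'   classification).
#' @export
setClass("TarSet",
    representation(transcripts = "TranscriptSet", membership = "integer",
                   tarInfo = "DataFrame"))

setValidity("TarSet", function(object) {
    if (length(object@membership) != length(object@transcripts@exons))
        return("membership must be parallel to transcripts")
    if (nrow(object@tarInfo) > 0 &&
        !all(object@membership %in% seq_len(nrow(object@tarInfo))))
        return("membership indices must point into tarInfo")
    TRUE
})

#' CohortConfig: parameters of the synthetic multi-tissue cohort
#'
#' Defaults emulate the study design the package targets: 3 correlated
#' "placental" target tissues against a 16-tissue background panel, planted
#' tissue-enriched genes at folds comfortably above the 4-fold calling
#' threshold, planted tissue-specific genes that are structurally zero in the
#' background, cassette exons with known inclusion levels and a subset with a
#' planted inclusion shift in the targets.
#'
#' @slot nGenes number of genes.
#' @slot nBackgroundTissues background panel size (default 16).
#' @slot nTargetTissues number of target tissues (default 3).
#' @slot nEnrichedPerTarget planted enriched genes per target tissue.
#' @slot nEnrichedShared planted genes enriched jointly in every target
#'   tissue (the shared signature that makes the targets cluster together).
#' @slot nSpecificPerTarget planted specific genes per target tissue.
#' @slot foldRange planted enrichment fold range; the low end must be > 4 so
#'   planted genes satisfy the caller's threshold by construction.
#' @slot baseLogMean,baseLogSd log-normal parameters of the base FPKM level.
#' @slot tissueLogSd standard deviation (natural-log scale) of per-tissue
#'   biological variation around the base level: every tissue deviates from
#'   the shared base profile gene by gene, as distinct real tissues do.
#' @slot targetCor correlation of the target tissues' biological deviations
#'   (a latent factor shared by the compartments of one organ); background
#'   tissues deviate independently.
#' @slot librarySizeRange per-tissue library size range (mapped fragments).
#' @slot nCassetteExons number of genes carrying a cassette exon.
#' @slot psiShiftFraction fraction of cassette exons with a planted shift.
#' @slot psiShiftSize planted |delta PSI| in (0, 1].
#' @slot junctionCoverageMean expected informative junction reads per exon
#'   per tissue.
#' @slot dispersion negative-binomial size parameter for fragment counts;
#'   \code{Inf} (the default) gives Poisson noise, smaller values add
#'   overdispersion; \code{0} disables noise (counts = rounded expectation).
#' @slot seed integer random seed.
#' @export
setClass("CohortConfig",
    representation(nGenes = "integer", nBackgroundTissues = "integer",
        nTargetTissues = "integer", nEnrichedPerTarget = "integer",
        nEnrichedShared = "integer",
        nSpecificPerTarget = "integer", foldRange = "numeric",
        baseLogMean = "numeric", baseLogSd = "numeric",
        tissueLogSd = "numeric", targetCor = "numeric",
        librarySizeRange = "numeric", nCassetteExons = "integer",
        psiShiftFraction = "numeric", psiShiftSize = "numeric",
        junctionCoverageMean = "numeric", dispersion = "numeric",
        seed = "integer"))

setValidity("CohortConfig", function(object) {
    cnt <- c(object@nGenes, object@nBackgroundTissues, object@nTargetTissues,
             object@nEnrichedPerTarget, object@nEnrichedShared,
             object@nSpecificPerTarget, object@nCassetteExons)
    if (any(cnt < 0L)) return("all counts must be >= 0")
    if (object@psiShiftSize <= 0 || object@psiShiftSize > 1)
        return("psiShiftSize must be in (0, 1]")
    if (object@psiShiftFraction < 0 || object@psiShiftFraction > 1)
        return("psiShiftFraction must be in [0, 1]")
    if (length(object@foldRange) != 2L || any(object@foldRange <= 4))
        return("foldRange must be two folds, both > 4 (the calling threshold)")
    if (diff(object@foldRange) < 0) return("foldRange must be non-decreasing")
    if (length(object@librarySizeRange) != 2L ||
        any(object@librarySizeRange < 1))
        return("librarySizeRange must be two positive sizes")
    if (object@tissueLogSd < 0)
        return("tissueLogSd must be >= 0")
    if (object@targetCor < 0 || object@targetCor >= 1)
        return("targetCor must be in [0, 1)")
    tot <- (object@nEnrichedPerTarget + object@nSpecificPerTarget) *
        object@nTargetTissues + object@nEnrichedShared
    if (tot > object@nGenes)
        return("more planted genes than genes in the cohort")
    if (object@nCassetteExons > object@nGenes)
        return("more cassette exons than genes")
    TRUE
})

#' Construct a CohortConfig
#'
#' @param nGenes,nBackgroundTissues,nTargetTissues,nEnrichedPerTarget
#'   see the class documentation.
#' @param nSpecificPerTarget,foldRange,baseLogMean,baseLogSd see the class
#'   documentation.
#' @param librarySizeRange,nCassetteExons,psiShiftFraction,psiShiftSize see
#'   the class documentation.
#' @param junctionCoverageMean,dispersion,seed see the class documentation.
#' @return a validated \code{CohortConfig}
#' @export
CohortConfig <- function(nGenes = 200L, nBackgroundTissues = 16L,
        nTargetTissues = 3L, nEnrichedPerTarget = 10L,
        nEnrichedShared = 5L, nSpecificPerTarget = 5L, foldRange = c(5, 50),
        baseLogMean = log(8), baseLogSd = 1,
        tissueLogSd = 1, targetCor = 0.5,
        librarySizeRange = c(2e6, 4e6), nCassetteExons = 50L,
        psiShiftFraction = 0.1, psiShiftSize = 0.3,
        junctionCoverageMean = 100, dispersion = Inf, seed = 1L) {
    new("CohortConfig", nGenes = as.integer(nGenes),
        nBackgroundTissues = as.integer(nBackgroundTissues),
        nTargetTissues = as.integer(nTargetTissues),
        nEnrichedPerTarget = as.integer(nEnrichedPerTarget),
        nEnrichedShared = as.integer(nEnrichedShared),
        nSpecificPerTarget = as.integer(nSpecificPerTarget),
        foldRange = as.numeric(foldRange),
        baseLogMean = as.numeric(baseLogMean),
        baseLogSd = as.numeric(baseLogSd),
        tissueLogSd = as.numeric(tissueLogSd),
        targetCor = as.numeric(targetCor),
        librarySizeRange = as.numeric(librarySizeRange),
        nCassetteExons = as.integer(nCassetteExons),
        psiShiftFraction = as.numeric(psiShiftFraction),
        psiShiftSize = as.numeric(psiShiftSize),
        junctionCoverageMean = as.numeric(junctionCoverageMean),
        dispersion = as.numeric(dispersion), seed = as.integer(seed))
}

#' SyntheticTruth: planted ground truth of a synthetic cohort
#'
#' @slot enrichedGenes named list: target tissue -> planted enriched gene ids.
#' @slot specificGenes named list: target tissue -> planted specific gene ids.
#' @slot truePsi events x tissues matrix of true inclusion levels.
#' @slot shiftedExons event ids with a planted inclusion shift of at least
#'   \code{psiShiftSize} in every target tissue.
#' @slot novelTars transcript ids of planted intergenic (novel) transcripts.
#' @slot novelExons \code{GRanges} of planted un-annotated internal exons.
#' @slot knownCopies transcript ids of jittered copies of annotated
#'   transcripts (terminal coordinates perturbed, splice sites intact).
#' @slot noiseTranscripts transcript ids of single-exon noise records.
#' @export
setClass("SyntheticTruth",
    representation(enrichedGenes = "list", specificGenes = "list",
        truePsi = "matrix", shiftedExons = "character",
        novelTars = "character", novelExons = "GRanges",
        knownCopies = "character", noiseTranscripts = "character"))

setValidity("SyntheticTruth", function(object) {
    both <- mapply(function(e, s) length(intersect(e, s)) > 0,
                   object@enrichedGenes,
                   object@specificGenes[names(object@enrichedGenes)])
    if (length(both) && any(unlist(both)))
        return("enriched and specific sets must be disjoint within a tissue")
    TRUE
})
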