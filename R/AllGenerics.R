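#' @include AllClasses.R
NULL

#' @export
setGeneric("exons", function(x, ...) standardGeneric("exons"))

#' @export
setGeneric("txId", function(x) standardGeneric("txId"))

#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @export
setGeneric("exonUnionLength", function(x, ...)
    standardGeneric("exonUnionLength"))

#' @export
setGeneric("internalExons", function(x, ...) standardGeneric("internalExons"))

#' @export
setGeneric("boundarySet", function(x, ...) standardGeneric("boundarySet"))

#' @export
setGeneric("computeFPKM", function(x, ...) standardGeneric("computeFPKM"))

#' @export
setGeneric("fpkm", function(x) standardGeneric("fpkm"))

#' @export
setGeneric("librarySize", function(x) standardGeneric("librarySize"))

#' @export
setGeneric("tarInfo", function(x) standardGeneric("tarInfo"))

#' @export
setGeneric("tarMembership", function(x) standardGeneric("tarMembership"))

#' Accessors for TranscriptSet
#'
#' \code{exons} returns the per-transcript \code{GRangesList}; \code{txId}
#' and \code{geneId} the parallel id vectors.
#'
#' @param x a \code{TranscriptSet}
#' @param ... unused
#' @return \code{exons}: a \code{GRangesList}; \code{txId}, \code{geneId}:
#'   character vectors.
#' @aliases exons txId geneId exons,TranscriptSet-method
#'   txId,TranscriptSet-method geneId,TranscriptSet-method
#' @name TranscriptSet-accessors
#' @rdname TranscriptSet-accessors
#' @export
setMethod("exons", "TranscriptSet", function(x, ...) x@exons)

#' @rdname TranscriptSet-accessors
#' @export
setMethod("txId", "TranscriptSet", function(x) names(x@exons))

#' @rdname TranscriptSet-accessors
#' @export
setMethod("geneId", "TranscriptSet", function(x) x@geneId)

#' @describeIn TranscriptSet-accessors number of transcripts
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@exons))

#' @describeIn TranscriptSet-accessors subset by index, name or logical
#' @param i subscript
#' @export
setMethod("[", "TranscriptSet", function(x, i) {
    if (is.character(i))
        i <- match(i, names(x@exons))
    initialize(x, exons = x@exons[i], geneId = x@geneId[i])
})

setMethod("show", "TranscriptSet", function(object) {
    n <- length(object)
    cat(sprintf("TranscriptSet with %d transcript%s in %d gene%s\n",
        n, if (n == 1) "" else "s",
        length(unique(object@geneId)),
        if (length(unique(object@geneId)) == 1) "" else "s"))
    if (n > 0) {
        k <- S4Vectors::elementNROWS(object@exons)
        cat(sprintf("  exons per transcript: %d-%d (median %g)\n",
            min(k), max(k), stats::median(k)))
    }
})

#' Combine two TranscriptSet objects
#'
#' Used e.g. to merge several annotation sources before novelty calling;
#' duplicate transcripts (identical chrom/strand/exon chain) are dropped,
#' keeping the first occurrence.
#'
#' @param x,y,... \code{TranscriptSet} objects
#' @param deduplicate drop records with an identical exon chain
#' @return a \code{TranscriptSet}
#' @export
combineTranscriptSets <- function(x, y, ..., deduplicate = TRUE) {
    all <- c(list(x, y), list(...))
    ex <- do.call(c, lapply(all, function(a) a@exons))
    gid <- unlist(lapply(all, function(a) a@geneId), use.names = FALSE)
    if (anyDuplicated(names(ex)))
        names(ex) <- make.unique(names(ex))
    if (deduplicate) {
        key <- vapply(seq_along(ex), function(i) {
            g <- ex[[i]]
            paste(as.character(seqnames(g))[1], as.character(strand(g))[1],
                  paste(start(g), end(g), sep = "-", collapse = ","),
                  sep = "|")
        }, character(1))
        keep <- !duplicated(key)
        ex <- ex[keep]; gid <- gid[keep]
    }
    new("TranscriptSet", exons = ex, geneId = gid)
}

#' @describeIn TissueExpression-class derived FPKM assay (error if not yet
#'   computed; see \code{\link{computeFPKM}})
#' @param x a \code{TissueExpression}
#' @aliases fpkm librarySize
#' @export
setMethod("fpkm", "TissueExpression", function(x) {
    if (!"fpkm" %in% assayNames(x))
        stop("no fpkm assay yet; run computeFPKM() first")
    assay(x, "fpkm")
})

#' @describeIn TissueExpression-class per-tissue total mapped fragments
#' @export
setMethod("librarySize", "TissueExpression", function(x) {
    structure(colData(x)$librarySize, names = colnames(x))
})

#' @describeIn TarSet-class per-TAR summary table
#' @param x a \code{TarSet}
#' @aliases tarInfo tarMembership
#' @export
setMethod("tarInfo", "TarSet", function(x) x@tarInfo)

#' @describeIn TarSet-class integer TAR index per clustered transcript,
#'   named by transcript id
#' @export
setMethod("tarMembership", "TarSet", function(x) {
    structure(x@membership, names = names(x@transcripts@exons))
})

#' @describeIn TarSet-class the clustered transcripts
#' @export
setMethod("exons", "TarSet", function(x, ...) x@transcripts@exons)

setMethod("show", "TarSet", function(object) {
    nov <- object@tarInfo$novelty
    cat(sprintf("TarSet: %d TARs from %d multi-exon transcripts\n",
        nrow(object@tarInfo), length(object@membership)))
    if (!all(is.na(nov)))
        cat(sprintf("  novelty: %d known, %d novel\n",
            sum(nov == "known", na.rm = TRUE),
            sum(nov == "novel", na.rm = TRUE)))
})

setMethod("show", "CohortConfig", function(object) {
    cat("CohortConfig\n")
    cat(sprintf("  genes: %d (enriched %d + specific %d per target)\n",
        object@nGenes, object@nEnrichedPerTarget, object@nSpecificPerTarget))
    cat(sprintf("  tissues: %d target + %d background\n",
        object@nTargetTissues, object@nBackgroundTissues))
    cat(sprintf("  cassette exons: %d (%.0f%% shifted by %.2f)\n",
        object@nCassetteExons, 100 * object@psiShiftFraction,
        object@psiShiftSize))
    cat(sprintf("  seed: %d\n", object@seed))
})

setMethod("show", "SyntheticTruth", function(object) {
    cat(sprintf(paste0("SyntheticTruth: %d enriched / %d specific genes, ",
                       "%d shifted exons, %d novel TARs\n"),
        length(unlist(object@enrichedGenes)),
        length(unlist(object@specificGenes)),
        length(object@shiftedExons), length(object@novelTars)))
})
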