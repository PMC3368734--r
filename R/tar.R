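#' @include AllClasses.R AllGenerics.R annotation.R
#' @importFrom igraph make_empty_graph add_edges components
NULL

#' Drop single-exon transcripts
#'
#' Reconstructed transcript termini are unreliable, so single-exon records
#' carry no trustworthy boundary at all and are removed (with a notice of
#' the removed count) before TAR clustering.
#'
#' @param x a \code{TranscriptSet}
#' @return a \code{TranscriptSet} of multi-exon transcripts, order
#'   preserved
#' @export
filterMultiExon <- function(x) {
    n <- S4Vectors::elementNROWS(exons(x))
    removed <- sum(n < 2L)
    message("removed ", removed, " single-exon transcript(s) of ",
            length(x))
    x[n >= 2L]
}

#' Do two transcripts overlap in the TAR sense?
#'
#' True when the transcripts lie on the same chromosome and strand and
#' share at least one splice-site boundary (\code{\link{boundarySet}});
#' transcript termini never count, and mere span overlap is not enough.
#'
#' @param x,y \code{TranscriptSet}s of length 1 (or the first transcript of
#'   each is used)
#' @return logical
#' @export
transcriptsOverlap <- function(x, y) {
    kx <- .boundaryKeys(x[1L])[[1L]]
    ky <- .boundaryKeys(y[1L])[[1L]]
    length(intersect(kx, ky)) > 0
}

#' Cluster multi-exon transcripts into transcriptional active regions
#'
#' TARs are the connected components of the graph whose edges link
#' transcripts sharing at least one splice-site boundary on the same strand
#' (so chains A-B-C merge even when A and C share nothing directly). TAR
#' ids are assigned deterministically in (chromosome, span start, strand)
#' order.
#'
#' @param x a \code{TranscriptSet}; all transcripts must be multi-exon
#'   (run \code{\link{filterMultiExon}} first)
#' @return a \code{\link{TarSet}} with novelty not yet classified
#' @export
clusterTars <- function(x) {
    nEx <- S4Vectors::elementNROWS(exons(x))
    if (any(nEx < 2L))
        stop("single-exon transcripts present; run filterMultiExon() first")
    n <- length(x)
    keys <- .boundaryKeys(x)
    flatKeys <- unlist(keys, use.names = FALSE)
    owner <- rep(seq_len(n), S4Vectors::elementNROWS(keys))
    # transcripts sharing a boundary key: chain edges within each key group
    byKey <- split(owner, flatKeys)
    edges <- do.call(rbind, lapply(byKey[lengths(byKey) > 1L], function(v)
        cbind(v[-length(v)], v[-1L])))
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (!is.null(edges))
        g <- igraph::add_edges(g, as.vector(t(edges)))
    memb <- igraph::components(g)$membership
    # deterministic TAR order: (chrom, span start, strand)
    flat <- unlist(exons(x), use.names = FALSE)
    grp <- rep(seq_len(n), nEx)
    chrom1 <- tapply(as.character(seqnames(flat)), grp, `[`, 1L)
    strand1 <- tapply(as.character(strand(flat)), grp, `[`, 1L)
    spanS <- tapply(start(flat), grp, min)
    spanE <- tapply(end(flat), grp, max)
    tChrom <- tapply(chrom1, memb, `[`, 1L)
    tStrand <- tapply(strand1, memb, `[`, 1L)
    tS <- tapply(spanS, memb, min)
    tE <- tapply(spanE, memb, max)
    ord <- order(tChrom, tS, tStrand)
    rank <- integer(length(ord)); rank[ord] <- seq_along(ord)
    newMemb <- rank[memb]
    info <- DataFrame(
        tar_id = sprintf("TAR%05d", seq_along(ord)),
        chrom = as.character(tChrom[ord]),
        start = as.integer(tS[ord]), end = as.integer(tE[ord]),
        strand = as.character(tStrand[ord]),
        nMembers = as.integer(table(factor(newMemb,
                                           levels = seq_along(ord)))),
        novelty = NA_character_)
    new("TarSet", transcripts = x, membership = as.integer(newMemb),
        tarInfo = info)
}

#' Classify TARs as known or novel against an annotation
#'
#' A TAR is novel when none of its member transcripts shares a splice-site
#' boundary (same chromosome and strand) with any annotated transcript —
#' span overlap with a known gene does not make a TAR known; only a shared
#' boundary does. The annotation side uses splice-site boundaries too
#' (transcript termini excluded), keeping the definition symmetric.
#'
#' @param tars a \code{\link{TarSet}} from \code{\link{clusterTars}}
#' @param annotation a \code{TranscriptSet} of annotated transcripts
#'   (concatenate sources with \code{\link{combineTranscriptSets}})
#' @return the \code{TarSet} with the \code{novelty} column filled
#' @export
classifyTarNovelty <- function(tars, annotation) {
    annKeys <- unique(unlist(.boundaryKeys(annotation), use.names = FALSE))
    keys <- .boundaryKeys(tars@transcripts)
    txKnown <- vapply(keys, function(kk) any(kk %in% annKeys), logical(1))
    tarKnown <- tapply(txKnown, tars@membership, any)
    nov <- rep("novel", nrow(tars@tarInfo))
    nov[as.integer(names(tarKnown))[tarKnown]] <- "known"
    tars@tarInfo$novelty <- nov
    tars
}

#' Classify internal exons of annotation-overlapping TARs
#'
#' Each internal exon of each member transcript of the known
#' (annotation-overlapping) TARs falls into exactly one of four classes:
#' \describe{
#'   \item{annotated}{identical start and end to some annotated exon}
#'   \item{one_end_shared}{start shared with an annotated exon start, or
#'     end shared with an annotated exon end, but no exact match}
#'   \item{overlap_no_shared_end}{intersects an annotated exon without
#'     sharing either end}
#'   \item{no_overlap}{no sequence overlap with any annotated exon (e.g. a
#'     novel exon inside an intron)}
#' }
#' Edge sharing is tested on genomic coordinates per strand.
#'
#' @param tars a novelty-classified \code{\link{TarSet}}
#' @param annotation a \code{TranscriptSet}
#' @param tarIds which TARs to classify; default all known TARs. Asking
#'   for a novel TAR is an error.
#' @return list with \code{perExon} (a \code{DataFrame}: tar_id,
#'   transcript_id, chrom, start, end, strand, category), \code{tally}
#'   (named count vector over the four categories) and \code{perTar}
#'   (TARs x categories count matrix)
#' @export
classifyInternalExons <- function(tars, annotation, tarIds = NULL) {
    info <- tars@tarInfo
    if (all(is.na(info$novelty)))
        stop("run classifyTarNovelty() first")
    if (is.null(tarIds))
        tarIds <- info$tar_id[info$novelty == "known"]
    sel <- match(tarIds, info$tar_id)
    if (anyNA(sel))
        stop("unknown TAR id(s)")
    if (any(info$novelty[sel] == "novel"))
        stop("internal-exon classification is defined only for ",
             "annotation-overlapping (known) TARs")
    keep <- tars@membership %in% sel
    ts <- tars@transcripts[keep]
    memb <- tars@membership[keep]
    ie <- internalExons(ts)
    nIE <- S4Vectors::elementNROWS(ie)
    flat <- unlist(ie, use.names = FALSE)
    annEx <- unlist(exons(annotation), use.names = FALSE)
    cats <- c("annotated", "one_end_shared", "overlap_no_shared_end",
              "no_overlap")
    if (length(flat) == 0L) {
        tal <- stats::setNames(integer(4), cats)
        return(list(perExon = DataFrame(tar_id = character(0),
                        transcript_id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), category = character(0)),
                    tally = tal,
                    perTar = matrix(0L, 0, 4,
                                    dimnames = list(NULL, cats))))
    }
    cs <- function(g) paste0(as.character(seqnames(g)), ":",
                             as.character(strand(g)))
    exact <- paste0(cs(flat), ":", start(flat), "-", end(flat)) %in%
        paste0(cs(annEx), ":", start(annEx), "-", end(annEx))
    startShared <- paste0(cs(flat), ":s", start(flat)) %in%
        paste0(cs(annEx), ":s", start(annEx))
    endShared <- paste0(cs(flat), ":e", end(flat)) %in%
        paste0(cs(annEx), ":e", end(annEx))
    anyOv <- IRanges::overlapsAny(flat, annEx, ignore.strand = FALSE)
    category <- ifelse(exact, "annotated",
        ifelse(startShared | endShared, "one_end_shared",
            ifelse(anyOv, "overlap_no_shared_end", "no_overlap")))
    exTar <- info$tar_id[rep(memb, nIE)]
    perExon <- DataFrame(
        tar_id = exTar,
        transcript_id = rep(names(exons(ts)), nIE),
        chrom = as.character(seqnames(flat)),
        start = start(flat), end = end(flat),
        strand = as.character(strand(flat)),
        category = category)
    tally <- stats::setNames(
        as.integer(table(factor(category, levels = cats))), cats)
    perTar <- as.matrix(table(factor(exTar, levels = info$tar_id[sel]),
                              factor(category, levels = cats)))
    list(perExon = perExon, tally = tally, perTar = perTar)
}

#' Quantify and classify novel-TAR expression across tissues
#'
#' Treats the exon union of each TAR's member transcripts as a gene model,
#' computes FPKM exactly as for annotated genes, and applies the
#' tissue-enriched and tissue-specific callers.
#'
#' @param tars a novelty-classified \code{\link{TarSet}}
#' @param counts TARs x tissues fragment-count matrix; rownames are TAR ids
#' @param librarySize per-tissue total mapped fragments
#' @param target target tissue name
#' @param background background tissue names
#' @param minFpkm,minFold enrichment thresholds (defaults 1 and 4)
#' @param minTargetFpkm specificity FPKM filter (default 0.3)
#' @param novelOnly restrict to novel TARs (default TRUE)
#' @return list with \code{expression} (a \code{\link{TissueExpression}}
#'   with fpkm), \code{enriched} and \code{specific} call tables
#' @export
novelTarExpression <- function(tars, counts, librarySize, target,
        background, minFpkm = 1, minFold = 4, minTargetFpkm = 0.3,
        novelOnly = TRUE) {
    info <- tars@tarInfo
    ids <- if (novelOnly) {
        if (all(is.na(info$novelty)))
            stop("run classifyTarNovelty() first")
        info$tar_id[info$novelty == "novel"]
    } else info$tar_id
    ids <- intersect(ids, rownames(counts))
    # exon union length per TAR from its member transcripts
    flat <- unlist(exons(tars@transcripts), use.names = FALSE)
    grp <- info$tar_id[rep(tars@membership,
        S4Vectors::elementNROWS(exons(tars@transcripts)))]
    uLen <- sum(width(GenomicRanges::reduce(
        GenomicRanges::split(flat, grp))))
    te <- TissueExpression(counts[ids, , drop = FALSE],
                           librarySize = librarySize,
                           unionLength = uLen[ids])
    te <- computeFPKM(te)
    list(expression = te,
         enriched = callTissueEnriched(te, target, background,
                                       minFpkm = minFpkm,
                                       minFold = minFold),
         specific = callTissueSpecific(te, target, background,
                                       minTargetFpkm = minTargetFpkm))
}
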