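#' @include AllClasses.R AllGenerics.R
NULL

#' Read transcript models from GTF or BED12
#'
#' Coordinates are converted to the internal 1-based closed convention at
#' this edge: GTF is 1-based inclusive already, BED12 blocks are 0-based
#' half-open. Records without a strand are rejected (the downstream
#' shared-boundary overlap rule is strand-conditioned). Exon overlap within
#' a transcript is a validation error.
#'
#' @param path file path.
#' @param format \code{"gtf"}, \code{"bed12"} or \code{"auto"} (from the
#'   file extension).
#' @return a \code{\link{TranscriptSet}}
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1\tdemo\texon\t101\t200\t.\t+\t.",
#'   'gene_id "g1"; transcript_id "t1";'), gtf)
#' ts <- readAnnotation(gtf)
#' GenomicRanges::start(exons(ts)[["t1"]])  # 101
#' @export
readAnnotation <- function(path, format = c("auto", "gtf", "bed12")) {
    format <- match.arg(format)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- switch(ext, gtf = "gtf", gff = "gtf", bed = "bed12",
                         bed12 = "bed12",
                         stop("cannot infer format from extension '.", ext,
                              "'; pass format="))
    }
    if (!file.exists(path))
        stop("no such file: ", path)
    .prevalidateLines(path, format)
    if (format == "gtf") {
        gr <- rtracklayer::import(path, format = "gtf")
        gr <- gr[gr$type == "exon"]
        if (length(gr) == 0L)
            return(TranscriptSet(GRangesList()))
        if (is.null(gr$transcript_id) || anyNA(gr$transcript_id))
            stop("GTF exon records must carry a transcript_id attribute")
        if (any(as.character(strand(gr)) == "*"))
            stop("strandless GTF records are not supported")
        grl <- GenomicRanges::split(gr, gr$transcript_id)
        gid <- vapply(grl, function(g)
            as.character(g$gene_id[1]), character(1))
        gid[is.na(gid)] <- names(grl)[is.na(gid)]
    } else {
        bed <- rtracklayer::import(path, format = "bed")
        if (length(bed) == 0L)
            return(TranscriptSet(GRangesList()))
        if (any(as.character(strand(bed)) == "*"))
            stop("strandless BED12 records are not supported")
        if (is.null(bed$name) || anyNA(bed$name))
            bed$name <- paste0("tx", seq_along(bed))
        grl <- rtracklayer::blocks(bed)      # absolute, 1-based closed
        names(grl) <- bed$name
        # BED12 carries no gene grouping; name doubles as gene id unless the
        # name is "<gene>|<transcript>"
        parts <- strsplit(bed$name, "|", fixed = TRUE)
        gid <- vapply(parts, `[`, character(1), 1L)
        names(grl) <- vapply(parts, function(p) p[length(p)], character(1))
    }
    ts <- try(TranscriptSet(grl, geneId = unname(gid)), silent = TRUE)
    if (is(ts, "try-error"))
        stop("annotation failed validation: ",
             attr(ts, "condition")$message)
    ts
}

# cheap structural pre-scan so malformed lines are reported with a line number
.prevalidateLines <- function(path, format) {
    lines <- readLines(path, warn = FALSE)
    body <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
    nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    want <- if (format == "gtf") 9L else 12L
    bad <- which(body)[nf < want]
    if (length(bad))
        stop(sprintf("malformed %s line %d: expected >= %d tab-separated fields, got %d",
                     toupper(format), bad[1], want, nf[which(which(body) == bad[1])]))
    invisible(TRUE)
}

#' Write transcript models to GTF or BED12
#'
#' The inverse of \code{\link{readAnnotation}}; a written file re-reads to
#' identical coordinates in either dialect.
#'
#' @param x a \code{TranscriptSet}.
#' @param path output file path.
#' @param format \code{"gtf"}, \code{"bed12"} or \code{"auto"}.
#' @return \code{path}, invisibly
#' @export
writeAnnotation <- function(x, path, format = c("auto", "gtf", "bed12")) {
    format <- match.arg(format)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- switch(ext, gtf = "gtf", bed = "bed12", bed12 = "bed12",
                         stop("cannot infer format from extension"))
    }
    if (format == "gtf") {
        flat <- unlist(x@exons, use.names = FALSE)
        n <- S4Vectors::elementNROWS(x@exons)
        mcols(flat)$type <- "exon"
        mcols(flat)$transcript_id <- rep(names(x@exons), n)
        mcols(flat)$gene_id <- rep(x@geneId, n)
        mcols(flat)$source <- "placentome"
        rtracklayer::export(flat, path, format = "gtf")
    } else {
        grl <- x@exons
        # encode gene id into the name so BED12 round-trips gene grouping
        nm <- ifelse(x@geneId == names(grl), names(grl),
                     paste(x@geneId, names(grl), sep = "|"))
        names(grl) <- nm
        rtracklayer::export(grl, path, format = "bed")
    }
    invisible(path)
}

#' Exon-union length per gene
#'
#' The denominator of the FPKM formula: the number of genomic bases covered
#' by at least one exon of any isoform of the gene ("exon union" counting,
#' which sidesteps read assignment across isoforms).
#'
#' @param x a \code{TranscriptSet}
#' @param ... unused
#' @return named numeric vector, one length in bp per gene
#' @examples
#' grl <- GenomicRanges::GRangesList(
#'   a = GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200), "+"),
#'   b = GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 300), "+"))
#' exonUnionLength(TranscriptSet(grl, geneId = c("g", "g")))  # g: 200
#' @export
setMethod("exonUnionLength", "TranscriptSet", function(x, ...) {
    if (length(x) == 0L)
        return(structure(numeric(0), names = character(0)))
    flat <- unlist(x@exons, use.names = FALSE)
    grp <- rep(x@geneId, S4Vectors::elementNROWS(x@exons))
    byGene <- GenomicRanges::split(flat, grp)
    lens <- sum(width(GenomicRanges::reduce(byGene)))
    structure(as.numeric(lens), names = names(lens))
})

#' Internal exons of each transcript
#'
#' All exons except the first and last in genomic order; transcripts with
#' two or fewer exons contribute none. Only internal exons are compared
#' against annotation in the TAR novelty analysis, because reconstructed
#' transcript termini are unreliable.
#'
#' @param x a \code{TranscriptSet}
#' @param ... unused
#' @return a \code{GRangesList} parallel to \code{x} (possibly with empty
#'   elements)
#' @export
setMethod("internalExons", "TranscriptSet", function(x, ...) {
    n <- S4Vectors::elementNROWS(x@exons)
    flat <- unlist(x@exons, use.names = FALSE)
    pos <- sequence(n)
    keep <- pos > 1L & pos < rep(n, n)
    out <- GenomicRanges::split(
        flat[keep],
        factor(rep(seq_along(n), n)[keep], levels = seq_along(n)))
    names(out) <- names(x@exons)
    out
})

#' Splice-site boundary coordinates of each transcript
#'
#' All exon edges except the transcript's outermost start and end, i.e. the
#' donor and acceptor positions. For a transcript with k exons the set has
#' exactly 2k - 2 coordinates; single-exon transcripts have none. Two
#' transcripts on the same chromosome and strand "overlap" in the TAR sense
#' when these sets intersect.
#'
#' Coordinates are reported in the between-base convention (an exon covering
#' 1-based positions s..e has edges s-1 and e), so donor and acceptor edges
#' of adjacent exons can never collide.
#'
#' @param x a \code{TranscriptSet}
#' @param ... unused
#' @return an \code{IntegerList} of sorted boundary coordinates, parallel to
#'   \code{x}
#' @export
setMethod("boundarySet", "TranscriptSet", function(x, ...) {
    n <- S4Vectors::elementNROWS(x@exons)
    flat <- unlist(x@exons, use.names = FALSE)
    grp <- rep(seq_along(n), n)
    pos <- sequence(n)
    lefts <- start(flat) - 1L    # between-base left edge
    rights <- end(flat)          # between-base right edge
    keepL <- pos > 1L            # drop transcript 5'-most start
    keepR <- pos < rep(n, n)     # drop transcript 3'-most end
    coords <- c(lefts[keepL], rights[keepR])
    cgrp <- c(grp[keepL], grp[keepR])
    out <- IRanges::IntegerList(lapply(
        split(coords, factor(cgrp, levels = seq_along(n))), sort))
    names(out) <- names(x@exons)
    out
})

# "chrom:strand:coord" keys for fast boundary hashing across transcript sets
.boundaryKeys <- function(x) {
    bs <- boundarySet(x)
    n <- S4Vectors::elementNROWS(bs)
    flat1 <- vapply(seq_along(x@exons), function(i) {
        g <- x@exons[[i]]
        paste0(as.character(seqnames(g))[1], ":", as.character(strand(g))[1])
    }, character(1))
    keys <- paste0(rep(flat1, n), ":", unlist(bs, use.names = FALSE))
    out <- split(keys, factor(rep(seq_along(bs), n), levels = seq_along(bs)))
    names(out) <- names(x@exons)
    out
}
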