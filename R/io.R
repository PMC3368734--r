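#' @include AllClasses.R AllGenerics.R
NULL

#' Write / read the gene-level count table
#'
#' Plain TSV with a \code{gene_id} column followed by one column per
#' tissue; the companion library-size file has columns \code{tissue},
#' \code{librarySize}.
#'
#' @param x a \code{\link{TissueExpression}}
#' @param countsPath,libPath output paths
#' @return \code{countsPath}, invisibly
#' @export
writeExpression <- function(x, countsPath, libPath) {
    cts <- assay(x, "counts")
    write.table(data.frame(gene_id = rownames(cts), cts,
                           check.names = FALSE),
                countsPath, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(tissue = colnames(cts),
                           librarySize = colData(x)$librarySize),
                libPath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(countsPath)
}

#' @rdname writeExpression
#' @param countsPath,libPath input paths
#' @param unionLength named per-gene exon-union lengths (e.g. from
#'   \code{\link{exonUnionLength}} on the annotation)
#' @export
readExpression <- function(countsPath, libPath, unionLength) {
    cts <- read.delim(countsPath, check.names = FALSE)
    rn <- cts$gene_id
    cts <- as.matrix(cts[, -1, drop = FALSE])
    rownames(cts) <- rn
    lib <- read.delim(libPath)
    TissueExpression(cts, librarySize = lib$librarySize[
                         match(colnames(cts), lib$tissue)],
                     unionLength = unionLength)
}

#' Write / read the junction-count table
#'
#' Long-format TSV, one row per event and tissue: \code{event_id},
#' \code{gene_id}, \code{chrom}, \code{start}, \code{end}, \code{strand},
#' \code{tissue}, \code{ujc}, \code{djc}, \code{sjc}. Exon coordinates are
#' written 1-based inclusive (the GTF convention).
#'
#' @param x a \code{\link{SpliceEventSet}}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeJunctionCounts <- function(x, path) {
    rr <- rowRanges(x)
    nt <- ncol(x)
    long <- data.frame(
        event_id = rep(rownames(x), nt),
        gene_id = rep(mcols(rr)$gene_id, nt),
        chrom = rep(as.character(seqnames(rr)), nt),
        start = rep(start(rr), nt), end = rep(end(rr), nt),
        strand = rep(as.character(strand(rr)), nt),
        tissue = rep(colnames(x), each = nrow(x)),
        ujc = as.vector(assay(x, "ujc")),
        djc = as.vector(assay(x, "djc")),
        sjc = as.vector(assay(x, "sjc")))
    write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeJunctionCounts
#' @export
readJunctionCounts <- function(path) {
    long <- read.delim(path)
    evs <- unique(long[, c("event_id", "gene_id", "chrom", "start", "end",
                           "strand")])
    tissues <- unique(long$tissue)
    mk <- function(col) {
        m <- matrix(0L, nrow(evs), length(tissues),
                    dimnames = list(evs$event_id, tissues))
        m[cbind(match(long$event_id, evs$event_id),
                match(long$tissue, tissues))] <- long[[col]]
        m
    }
    exon <- GRanges(evs$chrom, IRanges(evs$start, evs$end), evs$strand,
                    gene_id = evs$gene_id)
    names(exon) <- evs$event_id
    SpliceEventSet(exon, ujc = mk("ujc"), djc = mk("djc"), sjc = mk("sjc"))
}

#' Write / read the planted-truth sidecar
#'
#' YAML with documented keys: \code{enriched_genes} and
#' \code{specific_genes} (per target tissue), \code{shifted_exons},
#' \code{true_psi} (per event, per tissue), \code{novel_tars},
#' \code{novel_exons} (as \code{chrom:start-end:strand} strings),
#' \code{known_copies}, \code{noise_transcripts}.
#'
#' @param truth a \code{\link{SyntheticTruth}}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeTruth <- function(truth, path) {
    ne <- truth@novelExons
    obj <- list(
        enriched_genes = lapply(truth@enrichedGenes, as.list),
        specific_genes = lapply(truth@specificGenes, as.list),
        shifted_exons = as.list(truth@shiftedExons),
        true_psi = if (nrow(truth@truePsi)) apply(truth@truePsi, 1,
                       as.list, simplify = FALSE) else list(),
        novel_tars = as.list(truth@novelTars),
        novel_exons = as.list(sprintf("%s:%d-%d:%s",
            as.character(seqnames(ne)), start(ne), end(ne),
            as.character(strand(ne)))),
        known_copies = as.list(truth@knownCopies),
        noise_transcripts = as.list(truth@noiseTranscripts))
    writeLines(yaml::as.yaml(obj, precision = 15), path)
    invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
    y <- yaml::read_yaml(path)
    toChr <- function(x) as.character(unlist(x))
    psi <- if (length(y$true_psi)) {
        rows <- lapply(y$true_psi, unlist)
        m <- do.call(rbind, rows)
        rownames(m) <- names(y$true_psi)
        m
    } else matrix(numeric(0), 0, 0)
    ne <- if (length(y$novel_exons)) {
        parts <- regmatches(toChr(y$novel_exons),
            regexec("^(.+):(\\d+)-(\\d+):([+-])$", toChr(y$novel_exons)))
        GRanges(vapply(parts, `[`, "", 2),
                IRanges(as.integer(vapply(parts, `[`, "", 3)),
                        as.integer(vapply(parts, `[`, "", 4))),
                vapply(parts, `[`, "", 5))
    } else GRanges()
    new("SyntheticTruth",
        enrichedGenes = lapply(y$enriched_genes, toChr),
        specificGenes = lapply(y$specific_genes, toChr),
        truePsi = psi,
        shiftedExons = toChr(y$shifted_exons),
        novelTars = toChr(y$novel_tars),
        novelExons = ne,
        knownCopies = toChr(y$known_copies),
        noiseTranscripts = toChr(y$noise_transcripts))
}

#' Write a gene list (one id per line)
#'
#' @param ids character vector
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeGeneList <- function(ids, path) {
    writeLines(ids, path)
    invisible(path)
}

#' @rdname writeGeneList
#' @export
readGeneList <- function(path) {
    ids <- readLines(path, warn = FALSE)
    ids[nzchar(ids)]
}
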