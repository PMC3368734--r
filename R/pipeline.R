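#' @include AllClasses.R AllGenerics.R synthetic.R expression.R splice.R
#'   overlap.R tar.R io.R
NULL

.defaultConfig <- function() list(
    seed = 1L,
    cohort = list(
        nGenes = 200L, nBackgroundTissues = 16L, nTargetTissues = 3L,
        nEnrichedPerTarget = 10L, nEnrichedShared = 5L,
        nSpecificPerTarget = 5L,
        foldRange = c(5, 50), baseLogMean = log(8), baseLogSd = 1,
        tissueLogSd = 1, targetCor = 0.5,
        librarySizeRange = c(2e6, 4e6), nCassetteExons = 50L,
        psiShiftFraction = 0.1, psiShiftSize = 0.3,
        junctionCoverageMean = 100, dispersion = Inf),
    plant = list(nNovelTars = 5L, nNovelExons = 5L, nNoise = 10L,
                 geneListSize = 30L, geneListOddsRatio = 10),
    analysis = list(minFpkm = 1, minFold = 4, specificFpkmFilter = 0.3,
                    divergentMinFpkm = 5, divergentMinTissues = 8,
                    topK = 1000L, deltaC = 0.1, fdrCutoff = 0.1,
                    minInformative = 10L, bootstrapB = 1000L,
                    gridStep = 0.001),
    tissues = NULL)   # optional explicit target/background role override

.mergeConfig <- function(base, override) {
    for (nm in names(override)) {
        if (is.list(base[[nm]]) && is.list(override[[nm]]))
            base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
        else
            base[[nm]] <- override[[nm]]
    }
    base
}

#' Build a fully materialised pipeline configuration
#'
#' Returns the complete configuration with every default filled in, so the
#' report can echo the exact parameters in force — no hidden defaults at
#' run time. Overrides are given as (possibly nested) named lists, e.g.
#' \code{pipelineConfig(seed = 7, cohort = list(nGenes = 100))}.
#'
#' @param ... named overrides of the default configuration
#' @return nested configuration list
#' @export
pipelineConfig <- function(...) {
    .mergeConfig(.defaultConfig(), list(...))
}

# does a set of leaf labels form a clade of the hclust tree?
.isClade <- function(hc, leaves) {
    for (k in seq_len(length(hc$labels))) {
        memb <- stats::cutree(hc, k)
        for (cl in unique(memb)) {
            got <- names(memb)[memb == cl]
            if (setequal(got, leaves))
                return(TRUE)
        }
    }
    FALSE
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes, in dependency order: cohort generation, FPKM quantification
#' with enrichment/specificity calling and divergent-gene clustering,
#' differential-splicing testing of each target tissue against the pooled
#' background panel, gene-set overlap enrichment of the called enriched
#' genes against the planted gene list, and TAR clustering with novelty and
#' internal-exon classification. All stage outputs are written as TSV /
#' GTF / YAML under \code{outdir}; the returned report is derived entirely
#' from the stage outputs. Identical configuration and seed give
#' byte-identical outputs: every stochastic stage derives its own seed from
#' the master seed, so stages are individually reproducible.
#'
#' @param config a configuration list from \code{\link{pipelineConfig}}, a
#'   path to a YAML file of overrides, or \code{NULL} for the defaults
#' @param outdir output directory (created if needed)
#' @return the run report, invisibly: a nested list with per-stage record
#'   counts, the full parameter echo, seed and package version
#' @export
runPipeline <- function(config = NULL, outdir = tempfile("placentome_run")) {
    if (is.character(config))
        config <- yaml::read_yaml(config)
    config <- .mergeConfig(.defaultConfig(), if (is.null(config)) list()
                           else config)
    cfg <- do.call(CohortConfig, c(config$cohort, list(seed = config$seed)))
    tn <- tissueNames(cfg)
    if (!is.null(config$tissues)) {
        roles <- config$tissues
        if (length(intersect(roles$target, roles$background)))
            stop("target and background tissue sets overlap")
        known <- c(tn$target, tn$background)
        bad <- setdiff(c(roles$target, roles$background), known)
        if (length(bad))
            stop("unknown tissue(s) in config: ", paste(bad, collapse = ", "))
        tn <- roles
    }
    an <- config$analysis
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(outdir, f)

    ## stage 1: synthetic cohort
    cohort <- simulateCohort(cfg, nNovelTars = config$plant$nNovelTars,
        nNovelExons = config$plant$nNovelExons,
        nNoise = config$plant$nNoise)
    writeAnnotation(cohort$annotation, p("annotation.gtf"))
    writeAnnotation(cohort$reconstructed, p("reconstructed.gtf"))
    writeExpression(cohort$expression, p("counts.tsv"),
                    p("library_sizes.tsv"))
    writeJunctionCounts(cohort$events, p("junctions.tsv"))
    writeTruth(cohort$truth, p("truth.yaml"))
    geneList <- generateGeneList(cohort$truth,
        universe = unique(geneId(cohort$annotation)),
        targetOddsRatio = config$plant$geneListOddsRatio,
        size = min(config$plant$geneListSize, cfg@nGenes),
        seed = config$seed + 606L)
    writeGeneList(geneList, p("gene_list.txt"))

    ## stage 2: expression profiles
    te <- computeFPKM(cohort$expression)
    fp <- fpkm(te)
    write.table(data.frame(gene_id = rownames(fp), round(fp, 6),
                           check.names = FALSE),
                p("fpkm.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    calls <- do.call(rbind, lapply(tn$target, function(tt) {
        enr <- callTissueEnriched(te, tt, tn$background,
                                  minFpkm = an$minFpkm,
                                  minFold = an$minFold)
        spc <- callTissueSpecific(te, tt, tn$background,
                                  minTargetFpkm = an$specificFpkmFilter)
        DataFrame(enr, specific = spc$specific,
                  passesFpkmFilter = spc$passesFpkmFilter)
    }))
    write.table(as.data.frame(calls), p("enrichment_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    div <- suppressMessages(selectDivergentGenes(fp,
        minFpkm = an$divergentMinFpkm, minTissues = an$divergentMinTissues,
        topK = an$topK))
    write.table(div, p("divergent_genes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    clad <- FALSE
    if (nrow(div) >= 2) {
        # correlate on log scale so a handful of extreme FPKM values cannot
        # dominate the tissue tree
        cl <- suppressMessages(clusterProfiles(
            log2(fp[div$gene_id, , drop = FALSE] + 1)))
        clad <- .isClade(cl$tissueDendro, tn$target)
    }

    ## stage 3: differential splicing, each target vs pooled background
    splice <- lapply(tn$target, function(tt)
        callDifferentialExons(cohort$events, tt, tn$background,
            c = an$deltaC, fdrCutoff = an$fdrCutoff,
            minInformative = an$minInformative, B = an$bootstrapB,
            seed = config$seed + 707L, gridStep = an$gridStep))
    names(splice) <- tn$target
    for (tt in tn$target)
        write.table(as.data.frame(splice[[tt]]$results),
                    p(sprintf("splicing_%s.tsv", tt)), sep = "\t",
                    quote = FALSE, row.names = FALSE)

    ## stage 4: overlap enrichment of called enriched genes
    enrichedCalled <- unique(calls$gene_id[calls$enriched])
    universe <- unique(geneId(cohort$annotation))
    ovTab <- suppressMessages(
        buildOverlapTable(enrichedCalled, geneList, universe))
    fish <- fisherExact(ovTab, alternative = "greater")
    write.table(cbind(ovTab, oddsRatio = fish$oddsRatio,
                      pValue = fish$pValue),
                p("overlap.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)

    ## stage 5: TAR clustering and novelty
    multi <- suppressMessages(filterMultiExon(cohort$reconstructed))
    tars <- classifyTarNovelty(clusterTars(multi), cohort$annotation)
    info <- tarInfo(tars)
    write.table(as.data.frame(info), p("tars.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    exCls <- classifyInternalExons(tars, cohort$annotation)
    write.table(as.data.frame(exCls$perExon), p("exon_classes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    novelIds <- info$tar_id[info$novelty == "novel"]
    tarExpr <- NULL
    if (length(novelIds)) {
        tarCounts <- .demoTarCounts(novelIds, tn, librarySize(te),
                                    seed = config$seed + 808L)
        tarExpr <- novelTarExpression(tars, tarCounts, librarySize(te),
            target = tn$target[1], background = tn$background,
            minFpkm = an$minFpkm, minFold = an$minFold,
            minTargetFpkm = an$specificFpkmFilter)
        write.table(as.data.frame(DataFrame(tarExpr$enriched,
                specific = tarExpr$specific$specific)),
            p("novel_tar_expression.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
    }

    ## stage 6: report (derived from stage outputs, never hand-set)
    report <- list(
        version = as.character(utils::packageVersion("placentome")),
        seed = config$seed,
        parameters = config,
        synth = list(nGenes = length(unique(geneId(cohort$annotation))),
                     nTranscripts = length(cohort$annotation),
                     nCassetteExons = length(cohort$cassetteExons),
                     nReconstructed = length(cohort$reconstructed)),
        expression = list(
            nGenesQuantified = nrow(fp),
            enrichedPerTarget = vapply(tn$target, function(tt)
                sum(calls$enriched[calls$targetTissue == tt]), 0L),
            specificPerTarget = vapply(tn$target, function(tt)
                sum(calls$specific[calls$targetTissue == tt]), 0L),
            nDivergent = nrow(div),
            targetCladeRecovered = clad),
        splicing = lapply(splice, `[[`, "summary"),
        overlap = list(table = as.list(ovTab[1, c("a", "b", "c", "d")]),
                       oddsRatio = fish$oddsRatio, pValue = fish$pValue),
        tars = list(nMultiExon = length(multi), nTars = nrow(info),
                    nNovel = sum(info$novelty == "novel"),
                    exonClassTally = as.list(exCls$tally),
                    nNovelEnriched = if (is.null(tarExpr)) 0L else
                        sum(tarExpr$enriched$enriched),
                    nNovelSpecific = if (is.null(tarExpr)) 0L else
                        sum(tarExpr$specific$specific)))
    writeLines(yaml::as.yaml(report, precision = 15), p("report.yaml"))
    invisible(report)
}

# demo fragment counts for novel TARs: alternating specific-like (zero
# background) and enriched-like (10x the background level) patterns
.demoTarCounts <- function(ids, tn, librarySize, seed) {
    tissues <- c(tn$target, tn$background)
    withr::with_seed(as.integer(seed %% .Machine$integer.max), {
        m <- matrix(0L, length(ids), length(tissues),
                    dimnames = list(ids, tissues))
        for (i in seq_along(ids)) {
            if (i %% 2L == 1L) {           # specific-like
                m[i, tn$target] <- sample(20:200, length(tn$target), TRUE)
            } else {                       # enriched-like
                m[i, tn$background] <- sample(5:20, length(tn$background),
                                              TRUE)
                m[i, tn$target] <- sample(500:2000, length(tn$target), TRUE)
            }
        }
        m
    })
}
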