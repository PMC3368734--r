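cfgSmall <- CohortConfig(nGenes = 40L, nCassetteExons = 10L,
                         nEnrichedPerTarget = 3L, nEnrichedShared = 2L,
                         nSpecificPerTarget = 2L, seed = 5L)

test_that("generators are deterministic under a fixed seed", {
    a1 <- generateAnnotation(cfgSmall)
    a2 <- generateAnnotation(cfgSmall)
    expect_identical(as.data.frame(unlist(exons(a1$annotation))),
                     as.data.frame(unlist(exons(a2$annotation))))
    e1 <- generateExpression(cfgSmall, a1$annotation)
    e2 <- generateExpression(cfgSmall, a2$annotation)
    expect_identical(assay(e1$expression, "counts"),
                     assay(e2$expression, "counts"))
    j1 <- generateJunctionCounts(cfgSmall, a1$cassetteExons)
    j2 <- generateJunctionCounts(cfgSmall, a2$cassetteExons)
    expect_identical(assay(j1$events, "ujc"), assay(j2$events, "ujc"))
    gl1 <- generateGeneList(e1$truth, unique(geneId(a1$annotation)),
                            targetOddsRatio = 5, size = 10, seed = 3)
    gl2 <- generateGeneList(e1$truth, unique(geneId(a1$annotation)),
                            targetOddsRatio = 5, size = 10, seed = 3)
    expect_identical(gl1, gl2)
})

test_that("annotation layout honours the requested structure", {
    a <- generateAnnotation(cfgSmall)
    expect_length(a$cassetteExons, 10L)
    expect_true(all(S4Vectors::elementNROWS(exons(a$annotation)) >= 2L))
    # cassette exons are internal exons of their host gene
    host <- match(paste0(a$cassetteExons$gene_id, ".t1"),
                  txId(a$annotation))
    for (i in seq_along(a$cassetteExons)) {
        g <- exons(a$annotation)[[host[i]]]
        pos <- which(start(g) == start(a$cassetteExons)[i])
        expect_gt(pos, 1L)
        expect_lt(pos, length(g))
    }
    empty <- generateAnnotation(CohortConfig(nGenes = 0L,
        nCassetteExons = 0L, nEnrichedPerTarget = 0L, nEnrichedShared = 0L,
        nSpecificPerTarget = 0L))
    expect_length(empty$annotation, 0L)
})

test_that("planted expression respects its construction rules", {
    a <- generateAnnotation(cfgSmall)
    ex <- generateExpression(cfgSmall, a$annotation)
    cts <- assay(ex$expression, "counts")
    tn <- tissueNames(cfgSmall)
    # specific genes: structurally zero outside their own target
    for (tt in tn$target) {
        sg <- ex$truth@specificGenes[[tt]]
        expect_true(all(cts[sg, tn$background] == 0))
        expect_true(all(cts[sg, setdiff(tn$target, tt)] == 0))
    }
    # noise-free: measured fold equals planted fold up to count rounding
    cfg0 <- CohortConfig(nGenes = 40L, nCassetteExons = 10L,
        nEnrichedPerTarget = 3L, nEnrichedShared = 0L,
        nSpecificPerTarget = 0L, foldRange = c(10, 10),
        tissueLogSd = 0, dispersion = 0, seed = 5L)
    a0 <- generateAnnotation(cfg0)
    ex0 <- generateExpression(cfg0, a0$annotation)
    te0 <- computeFPKM(ex0$expression)
    fp <- fpkm(te0)
    for (tt in tissueNames(cfg0)$target) {
        eg <- ex0$truth@enrichedGenes[[tt]]
        fold <- fp[eg, tt] / rowMeans(fp[eg, tissueNames(cfg0)$background])
        expect_equal(unname(fold), rep(10, length(eg)), tolerance = 0.05)
    }
})

test_that("junction model is unbiased and hits its edge cases", {
    cfg <- CohortConfig(nGenes = 60L, nCassetteExons = 60L,
        nEnrichedPerTarget = 0L, nEnrichedShared = 0L,
        nSpecificPerTarget = 0L, nTargetTissues = 1L,
        nBackgroundTissues = 1L, junctionCoverageMean = 50,
        psiShiftFraction = 0, seed = 9L)
    a <- generateAnnotation(cfg)
    ev <- a$cassetteExons
    # PSI 1 forces SJC = 0; PSI 0 forces UJC = DJC = 0
    for (p in c(0, 1)) {
        tp <- matrix(p, length(ev), 2,
                     dimnames = list(names(ev),
                                     c("target_1", "background_01")))
        j <- generateJunctionCounts(cfg, ev, tp)
        if (p == 1) expect_true(all(assay(j$events, "sjc") == 0))
        else {
            expect_true(all(assay(j$events, "ujc") == 0))
            expect_true(all(assay(j$events, "djc") == 0))
        }
    }
    # Monte-Carlo unbiasedness: mean PSI-hat at 0.3 within 0.01
    # (10,000 event/tissue draws at coverage 50)
    cfgMC <- CohortConfig(nGenes = 5000L, nCassetteExons = 5000L,
        nEnrichedPerTarget = 0L, nEnrichedShared = 0L,
        nSpecificPerTarget = 0L, nTargetTissues = 1L,
        nBackgroundTissues = 1L, junctionCoverageMean = 50,
        psiShiftFraction = 0, seed = 13L)
    aMC <- generateAnnotation(cfgMC)
    tp <- matrix(0.3, 5000, 2,
                 dimnames = list(names(aMC$cassetteExons),
                                 c("target_1", "background_01")))
    j <- generateJunctionCounts(cfgMC, aMC$cassetteExons, tp)
    ps <- estimatePsi(as.vector(assay(j$events, "ujc")),
                      as.vector(assay(j$events, "djc")),
                      as.vector(assay(j$events, "sjc")))
    expect_lt(abs(mean(ps$psi, na.rm = TRUE) - 0.3), 0.01)
    # high coverage pins PSI-hat near truth
    cfgHi <- CohortConfig(nGenes = 1L, nCassetteExons = 1L,
        nEnrichedPerTarget = 0L, nEnrichedShared = 0L,
        nSpecificPerTarget = 0L, nTargetTissues = 1L,
        nBackgroundTissues = 1L, junctionCoverageMean = 10000,
        psiShiftFraction = 0, seed = 21L)
    aHi <- generateAnnotation(cfgHi)
    tp <- matrix(0.5, 1, 2, dimnames = list(names(aHi$cassetteExons),
                                            c("target_1", "background_01")))
    jHi <- generateJunctionCounts(cfgHi, aHi$cassetteExons, tp)
    psHi <- estimatePsi(assay(jHi$events, "ujc")[1, 1],
                        assay(jHi$events, "djc")[1, 1],
                        assay(jHi$events, "sjc")[1, 1])
    expect_lt(abs(psHi$psi - 0.5), 0.02)
})

test_that("reconstructed transcripts carry the planted truth labels", {
    a <- generateAnnotation(cfgSmall)
    r <- generateReconstructedTranscripts(cfgSmall, a$annotation,
        nNovelTars = 3L, nNovelExons = 3L, nNoise = 4L)
    ts <- r$transcripts
    # jittered copies keep the boundary set of their template
    bsRec <- boundarySet(ts)
    bsAnn <- boundarySet(a$annotation)
    for (id in txId(a$annotation)) {
        expect_equal(sort(bsRec[[paste0("rec_", id)]]),
                     sort(bsAnn[[id]]))
    }
    # planted intergenic transcripts share no boundary with annotation
    annKeys <- unique(unlist(placentome:::.boundaryKeys(a$annotation)))
    for (id in r$novelTars) {
        k <- placentome:::.boundaryKeys(ts[id])[[1]]
        expect_length(intersect(k, annKeys), 0L)
    }
    expect_length(r$noiseTranscripts, 4L)
    nEx <- S4Vectors::elementNROWS(exons(ts))[r$noiseTranscripts]
    expect_true(all(nEx == 1L))
})

test_that("gene lists track the requested overlap odds ratio limits", {
    a <- generateAnnotation(cfgSmall)
    e <- generateExpression(cfgSmall, a$annotation)
    uni <- unique(geneId(a$annotation))
    enriched <- unique(unlist(e$truth@enrichedGenes))
    inf <- generateGeneList(e$truth, uni, targetOddsRatio = Inf,
                            size = length(enriched) - 1, seed = 2)
    expect_true(all(inf %in% enriched))
    # odds ratio 1: overlap fraction near the enriched fraction on average
    fr <- vapply(1:200, function(s)
        mean(generateGeneList(e$truth, uni, targetOddsRatio = 1,
                              size = 15, seed = s) %in% enriched),
        numeric(1))
    expect_lt(abs(mean(fr) - length(enriched) / length(uni)), 0.05)
})

test_that("cohort files parse back through the I/O layer losslessly", {
    co <- simulateCohort(cfgSmall, nNovelTars = 2L, nNovelExons = 2L,
                         nNoise = 3L)
    d <- withr::local_tempdir()
    writeExpression(co$expression, file.path(d, "c.tsv"),
                    file.path(d, "l.tsv"))
    back <- readExpression(file.path(d, "c.tsv"), file.path(d, "l.tsv"),
                           exonUnionLength(co$annotation))
    expect_identical(assay(back, "counts"), assay(co$expression, "counts"))
    expect_equal(librarySize(back), librarySize(co$expression))
    writeJunctionCounts(co$events, file.path(d, "j.tsv"))
    jb <- readJunctionCounts(file.path(d, "j.tsv"))
    expect_identical(assay(jb, "ujc")[rownames(co$events),
                                      colnames(co$events)],
                     assay(co$events, "ujc"))
    writeTruth(co$truth, file.path(d, "t.yaml"))
    tb <- readTruth(file.path(d, "t.yaml"))
    expect_identical(tb@enrichedGenes, co$truth@enrichedGenes)
    expect_identical(tb@shiftedExons, co$truth@shiftedExons)
    expect_equal(tb@truePsi[rownames(co$truth@truePsi), ],
                 co$truth@truePsi, tolerance = 1e-12)
    expect_identical(start(tb@novelExons), start(co$truth@novelExons))
})
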