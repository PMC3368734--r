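#' @include AllClasses.R AllGenerics.R annotation.R
#' @importFrom stats rbinom rlnorm rnbinom rpois runif median sd cor dist
#'   hclust as.dist optimize pbeta p.adjust setNames
#' @importFrom utils read.delim write.table
NULL

# empty truth object; generators fill slots as they plant signal
.emptyTruth <- function() {
    new("SyntheticTruth", enrichedGenes = list(), specificGenes = list(),
        truePsi = matrix(numeric(0), 0, 0), shiftedExons = character(0),
        novelTars = character(0), novelExons = GRanges(),
        knownCopies = character(0), noiseTranscripts = character(0))
}

#' Tissue names of a synthetic cohort
#'
#' Target tissues are named \code{target_1 ...}; the background panel
#' \code{background_01 ...} (16 by default, mirroring a whole-body reference
#' panel such as Human Body Map 2.0).
#'
#' @param cfg a \code{\link{CohortConfig}}
#' @return list with \code{target} and \code{background} character vectors
#' @export
tissueNames <- function(cfg) {
    list(target = sprintf("target_%d", seq_len(cfg@nTargetTissues)),
         background = sprintf("background_%02d",
                              seq_len(cfg@nBackgroundTissues)))
}

#' Generate a synthetic gene annotation
#'
#' Lays \code{nGenes} multi-exon genes (one isoform each, 4-9 exons of
#' 150-350 bp) head-to-tail on synthetic chromosomes, 25 genes per
#' chromosome, with 8-15 kb intergenic gaps that leave room for planted
#' intergenic transcripts. A seeded subset of genes is flagged as carrying a
#' cassette exon: a skippable internal exon flanked by constitutive
#' neighbours.
#'
#' Deterministic given \code{cfg@seed}.
#'
#' @param cfg a \code{\link{CohortConfig}}
#' @return list with \code{annotation} (a \code{TranscriptSet}) and
#'   \code{cassetteExons} (a \code{GRanges} named by event id, with a
#'   \code{gene_id} column)
#' @export
generateAnnotation <- function(cfg) {
    validObject(cfg)
    withr::with_seed(cfg@seed + 101L, {
        n <- cfg@nGenes
        if (n == 0L)
            return(list(annotation = TranscriptSet(GRangesList()),
                        cassetteExons = GRanges(gene_id = character(0))))
        perChrom <- 25L
        nExon <- sample(4:9, n, replace = TRUE)
        gid <- sprintf("g%04d", seq_len(n))
        txid <- paste0(gid, ".t1")
        strandv <- sample(c("+", "-"), n, replace = TRUE)
        gap <- sample(8000:15000, n, replace = TRUE)
        m <- sum(nExon)
        w <- sample(150:350, m, replace = TRUE)
        intron <- sample(300:800, m, replace = TRUE)  # per exon; [1] unused
        grp <- rep(seq_len(n), nExon)
        exIdx <- sequence(nExon)
        chromOf <- paste0("chrS", (seq_len(n) - 1L) %/% perChrom + 1L)
        # step to each exon start: the gene gap for first exons (plus the
        # previous gene's last exon width within the chromosome), otherwise
        # previous exon width + intron; chromosomes restart at 1
        first <- exIdx == 1L
        prevW <- c(0L, w[-m])
        step <- ifelse(first, gap[grp] + prevW - 1L, prevW + intron)
        starts <- integer(m)
        for (ch in unique(chromOf)) {
            sel <- chromOf[grp] == ch
            st <- step[sel]
            st[1] <- gap[grp[sel][1]]
            starts[sel] <- 1L + cumsum(st)
        }
        flat <- GRanges(chromOf[grp], IRanges(starts, width = w),
                        strandv[grp])
        exl <- IRanges::relist(flat,
            IRanges::PartitioningByEnd(cumsum(nExon), names = txid))
        ts <- TranscriptSet(exl, geneId = gid)
        cassIdx <- sort(sample.int(n, cfg@nCassetteExons))
        cass <- GRanges()
        if (length(cassIdx)) {
            mid <- pmax(2L, pmin(nExon - 1L, (nExon + 1L) %/% 2L))
            pick <- cumsum(nExon) - nExon + mid   # flat index of the exon
            cass <- flat[pick[cassIdx]]
            mcols(cass)$gene_id <- gid[cassIdx]
            names(cass) <- sprintf("e%04d", seq_along(cassIdx))
        }
        list(annotation = ts, cassetteExons = cass)
    })
}

#' Generate fragment counts with planted enriched and specific genes
#'
#' Every gene gets a base FPKM level (log-normal, floored at 0.8 so that
#' background genes always leave a read footprint in every tissue), around
#' which each tissue varies biologically (log-normal, sd
#' \code{tissueLogSd}); the target tissues' deviations share a latent
#' factor with correlation \code{targetCor}, which is what makes the
#' compartments of the target organ cluster together. Planted enriched
#' genes are set, in their target tissue, to a fold drawn from
#' \code{foldRange} times the gene's realised mean background FPKM (so
#' the planted fold is the realised fold); planted specific genes are structurally zero outside
#' their target tissue and expressed at FPKM 0.55-0.95 inside it (detectable,
#' above the 0.3 reporting filter, and below the FPKM >= 1 enrichment floor
#' so the two planted classes stay disjoint). Expected fragment counts are
#' FPKM * (L/1000) * (N/1e6); observed counts are Poisson draws around them
#' (negative binomial when \code{dispersion} is finite; exactly the rounded
#' expectation when \code{dispersion = 0}).
#'
#' Library sizes are the drawn per-tissue totals of mapped fragments; the
#' modelled genes account for only a small fraction of them, as in a real
#' library where most fragments fall outside any one analysis gene set.
#'
#' @param cfg a \code{\link{CohortConfig}}
#' @param annotation the \code{TranscriptSet} from
#'   \code{\link{generateAnnotation}}
#' @return list with \code{expression} (a \code{\link{TissueExpression}})
#'   and \code{truth} (a \code{\link{SyntheticTruth}} with the planted gene
#'   sets filled in)
#' @export
generateExpression <- function(cfg, annotation) {
    stopifnot(length(annotation) > 0L)
    withr::with_seed(cfg@seed + 202L, {
        uLen <- exonUnionLength(annotation)
        genes <- names(uLen)
        tn <- tissueNames(cfg)
        tissues <- c(tn$target, tn$background)
        nT <- length(tissues)
        base <- pmax(rlnorm(length(genes), cfg@baseLogMean, cfg@baseLogSd), 0.8)
        # biological variation: each tissue deviates from the base profile;
        # target tissues share a latent factor (correlation targetCor), the
        # background tissues deviate independently. Mean-preserving on the
        # natural scale.
        nG <- length(genes)
        rho <- cfg@targetCor; s <- cfg@tissueLogSd
        zT <- sqrt(rho) * matrix(rnorm(nG), nG, cfg@nTargetTissues) +
            sqrt(1 - rho) * matrix(rnorm(nG * cfg@nTargetTissues), nG)
        zB <- matrix(rnorm(nG * cfg@nBackgroundTissues), nG)
        fpkmMat <- base * exp(s * cbind(zT, zB) - s^2 / 2)
        dimnames(fpkmMat) <- list(genes, tissues)
        nPlant <- (cfg@nEnrichedPerTarget + cfg@nSpecificPerTarget) *
            cfg@nTargetTissues + cfg@nEnrichedShared
        planted <- if (nPlant > 0) sample(genes, nPlant) else character(0)
        enriched <- specific <- stats::setNames(
            rep(list(character(0)), cfg@nTargetTissues), tn$target)
        # shared signature: enriched in every target with one common fold,
        # so the target tissues correlate with one another
        shared <- planted[seq_len(cfg@nEnrichedShared)]
        at <- cfg@nEnrichedShared
        sharedFold <- runif(length(shared), cfg@foldRange[1],
                            cfg@foldRange[2])
        bgMean <- function(g) rowMeans(fpkmMat[g, tn$background,
                                               drop = FALSE])
        fpkmMat[shared, tn$target] <- sharedFold * bgMean(shared)
        for (j in seq_len(cfg@nTargetTissues)) {
            eg <- planted[at + seq_len(cfg@nEnrichedPerTarget)]
            at <- at + cfg@nEnrichedPerTarget
            sg <- planted[at + seq_len(cfg@nSpecificPerTarget)]
            at <- at + cfg@nSpecificPerTarget
            enriched[[j]] <- sort(c(shared, eg)); specific[[j]] <- sort(sg)
            fold <- runif(length(eg), cfg@foldRange[1], cfg@foldRange[2])
            fpkmMat[eg, tn$target[j]] <- fold * bgMean(eg)
            fpkmMat[sg, ] <- 0
            fpkmMat[sg, tn$target[j]] <- runif(length(sg), 0.55, 0.95)
        }
        libSize <- round(runif(nT, cfg@librarySizeRange[1],
                               cfg@librarySizeRange[2]))
        mu <- fpkmMat * (uLen[genes] / 1000) *
            rep(libSize / 1e6, each = length(genes))
        counts <- .drawCounts(mu, cfg@dispersion)
        dimnames(counts) <- dimnames(mu)
        truth <- .emptyTruth()
        truth@enrichedGenes <- enriched
        truth@specificGenes <- specific
        list(expression = TissueExpression(counts, librarySize = libSize,
                                           unionLength = uLen),
             truth = truth)
    })
}

.drawCounts <- function(mu, dispersion) {
    out <- if (dispersion == 0) {
        round(mu)
    } else if (is.infinite(dispersion)) {
        matrix(rpois(length(mu), mu), nrow(mu))
    } else {
        matrix(rnbinom(length(mu), mu = mu, size = dispersion), nrow(mu))
    }
    out[mu == 0] <- 0      # structural zeros stay zero under any noise model
    storage.mode(out) <- "integer"
    out
}

#' Generate true inclusion levels for the cassette exons
#'
#' Null exons share one inclusion level across every tissue (drawn uniform
#' on 0.05-0.95). A seeded fraction \code{psiShiftFraction} of exons gets a
#' planted shift of exactly \code{psiShiftSize} in every target tissue, in a
#' randomly chosen feasible direction.
#'
#' @param cfg a \code{\link{CohortConfig}}
#' @param events cassette-exon \code{GRanges} from
#'   \code{\link{generateAnnotation}}
#' @return list with \code{truePsi} (events x tissues matrix) and
#'   \code{shiftedExons} (character)
#' @export
generateTruePsi <- function(cfg, events) {
    withr::with_seed(cfg@seed + 303L, {
        tn <- tissueNames(cfg)
        tissues <- c(tn$target, tn$background)
        ne <- length(events)
        base <- runif(ne, 0.05, 0.95)
        psi <- matrix(base, ne, length(tissues),
                      dimnames = list(names(events), tissues))
        nShift <- round(cfg@psiShiftFraction * ne)
        shifted <- if (nShift > 0) sort(sample(names(events), nShift))
                   else character(0)
        for (ev in shifted) {
            b <- psi[ev, 1]
            up <- b + cfg@psiShiftSize <= 0.98
            dn <- b - cfg@psiShiftSize >= 0.02
            dir <- if (up && dn) sample(c(1, -1), 1) else if (up) 1 else -1
            psi[ev, tn$target] <- b + dir * cfg@psiShiftSize
        }
        list(truePsi = psi, shiftedExons = shifted)
    })
}

#' Generate junction read counts for cassette exons
#'
#' Per event and tissue: the informative total n is Poisson with mean
#' \code{junctionCoverageMean}; k ~ Binomial(n, true PSI) inclusion events
#' each produce one read on the upstream and one on the downstream
#' junction, and the 2k inclusion-junction reads are split
#' Binomial(2k, 1/2) between UJC and DJC (so UJC and DJC differ,
#' exercising the (UJC+DJC)/2 averaging, while their mean I recovers k
#' exactly); the remaining n - k events are skipping reads (SJC). Under
#' this model PSI-hat = I/(I+S) = k/n is unbiased for the true PSI given
#' n > 0. With \code{dispersion = 0} the draws collapse to their rounded
#' expectations.
#'
#' @param cfg a \code{\link{CohortConfig}}
#' @param events cassette-exon \code{GRanges} (named by event id, with
#'   \code{gene_id})
#' @param truePsi events x tissues matrix; generated via
#'   \code{\link{generateTruePsi}} when \code{NULL}
#' @return list with \code{events} (a \code{\link{SpliceEventSet}}),
#'   \code{truePsi} and \code{shiftedExons}
#' @export
generateJunctionCounts <- function(cfg, events, truePsi = NULL) {
    shifted <- character(0)
    if (is.null(truePsi)) {
        tp <- generateTruePsi(cfg, events)
        truePsi <- tp$truePsi; shifted <- tp$shiftedExons
    }
    stopifnot(all(names(events) %in% rownames(truePsi)))
    withr::with_seed(cfg@seed + 404L, {
        psi <- truePsi[names(events), , drop = FALSE]
        ne <- nrow(psi); nt <- ncol(psi)
        if (cfg@dispersion == 0) {
            n <- matrix(round(cfg@junctionCoverageMean), ne, nt)
            k <- round(n * psi)
            u <- k
        } else {
            n <- matrix(rpois(ne * nt, cfg@junctionCoverageMean), ne, nt)
            k <- matrix(rbinom(ne * nt, as.vector(n), as.vector(psi)), ne, nt)
            u <- matrix(rbinom(ne * nt, 2L * as.vector(k), 0.5), ne, nt)
        }
        dimnames(n) <- dimnames(psi)
        d <- 2L * k - u; s <- n - k
        dimnames(u) <- dimnames(d) <- dimnames(s) <- dimnames(n)
        list(events = SpliceEventSet(events, ujc = u, djc = d, sjc = s),
             truePsi = truePsi, shiftedExons = shifted)
    })
}

#' Generate reconstructed transcripts with planted novelty
#'
#' Emulates the output of ab initio transcript reconstruction: (i) one copy
#' of every annotated transcript with jittered terminal coordinates but
#' intact splice sites; (ii) planted multi-exon transcripts in intergenic
#' space (the novel TARs); (iii) transcripts that add an un-annotated
#' internal exon inside an intron of a known gene; (iv) single-exon noise
#' records. Every record is labelled in the returned truth.
#'
#' @param cfg a \code{\link{CohortConfig}}
#' @param annotation the annotated \code{TranscriptSet}
#' @param nNovelTars planted intergenic transcripts
#' @param nNovelExons planted novel-internal-exon transcripts
#' @param nNoise planted single-exon noise records
#' @return list with \code{transcripts} (a \code{TranscriptSet}) and truth
#'   components \code{novelTars}, \code{novelExons}, \code{knownCopies},
#'   \code{noiseTranscripts}
#' @export
generateReconstructedTranscripts <- function(cfg, annotation,
        nNovelTars = 5L, nNovelExons = 5L, nNoise = 10L) {
    stopifnot(length(annotation) > 0L)
    withr::with_seed(cfg@seed + 505L, {
        ann <- exons(annotation)
        out <- list(); gid <- character(0)
        # (i) jittered copies: perturb outer termini, keep all splice sites
        for (i in seq_along(ann)) {
            g <- ann[[i]]
            k <- length(g)
            js <- sample(-50:50, 1L); je <- sample(-50:50, 1L)
            start(g)[1] <- max(1L, min(start(g)[1] + js, end(g)[1] - 20L))
            end(g)[k] <- max(start(g)[k] + 20L, end(g)[k] + je)
            out[[paste0("rec_", names(ann)[i])]] <- g
            gid <- c(gid, geneId(annotation)[i])
        }
        knownCopies <- paste0("rec_", names(ann))
        # intergenic gaps per chromosome for planting novel TARs
        flat <- unlist(ann, use.names = FALSE)
        occ <- GenomicRanges::reduce(flat, ignore.strand = TRUE)
        chromEnd <- tapply(end(flat), as.character(seqnames(flat)), max)
        gapList <- suppressWarnings(do.call(c, unname(lapply(
            split(occ, droplevels(seqnames(occ))), function(sp) {
                sp <- sort(sp)
                if (length(sp) < 2L)
                    return(GRanges())
                gs <- end(sp)[-length(sp)] + 1L
                ge <- start(sp)[-1L] - 1L
                keep <- ge - gs + 1L >= 4000L
                GRanges(as.character(seqnames(sp))[1],
                        IRanges(gs[keep], ge[keep]))
            }))))
        if (length(gapList) < nNovelTars)
            stop("not enough intergenic space to plant ", nNovelTars,
                 " novel TARs")
        pick <- sample(length(gapList), nNovelTars)
        novelTars <- character(0)
        for (j in seq_len(nNovelTars)) {
            gp <- gapList[pick[j]]
            nex <- sample(2:4, 1L)
            w <- sample(100:200, nex, replace = TRUE)
            intr <- sample(200:400, nex - 1L, replace = TRUE)
            span <- sum(w) + sum(intr)
            s0 <- start(gp) + 500L
            starts <- s0 + cumsum(c(0L, w[-nex] + intr))
            id <- sprintf("novelTAR%02d.t1", j)
            out[[id]] <- GRanges(seqnames(gp), IRanges(starts, width = w),
                                 sample(c("+", "-"), 1L))
            gid <- c(gid, sprintf("novelTAR%02d", j))
            novelTars <- c(novelTars, id)
        }
        # (iii) copies of known transcripts with one extra intronic exon
        multi <- which(S4Vectors::elementNROWS(ann) >= 2L)
        hosts <- sample(multi, min(nNovelExons, length(multi)))
        neChrom <- neStrand <- character(0); neStart <- neEnd <- integer(0)
        for (i in hosts) {
            g <- ann[[i]]
            iv <- which(start(g)[-1] - end(g)[-length(g)] >= 300L)
            if (!length(iv)) next
            pos <- if (length(iv) == 1L) iv else sample(iv, 1L)
            mid <- (end(g)[pos] + start(g)[pos + 1]) %/% 2L
            w <- sample(80:150, 1L)
            ne <- GRanges(seqnames(g)[1],
                          IRanges(mid - w %/% 2L, width = w), strand(g)[1])
            id <- paste0("novelexon_", names(ann)[i])
            out[[id]] <- sort(c(g, ne))
            gid <- c(gid, geneId(annotation)[i])
            neChrom <- c(neChrom, as.character(seqnames(g))[1])
            neStrand <- c(neStrand, as.character(strand(g))[1])
            neStart <- c(neStart, start(ne)); neEnd <- c(neEnd, end(ne))
        }
        novelExons <- GRanges(neChrom, IRanges(neStart, neEnd), neStrand)
        novelExonTx <- grep("^novelexon_", names(out), value = TRUE)
        # (iv) single-exon noise
        chroms <- names(chromEnd)
        noise <- character(0)
        for (j in seq_len(nNoise)) {
            ch <- sample(chroms, 1L)
            w <- sample(200:400, 1L)
            s <- sample.int(max(1L, chromEnd[[ch]] - w), 1L)
            id <- sprintf("noise%03d", j)
            out[[id]] <- GRanges(ch, IRanges(s, width = w),
                                 sample(c("+", "-"), 1L))
            gid <- c(gid, id)
            noise <- c(noise, id)
        }
        ts <- TranscriptSet(GRangesList(out, compress = TRUE), geneId = gid)
        list(transcripts = ts, novelTars = novelTars,
             novelExons = novelExons, novelExonTranscripts = novelExonTx,
             knownCopies = knownCopies, noiseTranscripts = noise)
    })
}

#' Sample an annotation-style gene list with a target overlap odds ratio
#'
#' Emulates an external disease- or phenotype-gene list whose overlap with
#' the planted enriched genes has a requested expected odds ratio: members
#' of the planted enriched set are sampled with weight
#' \code{targetOddsRatio}, all other universe genes with weight 1.
#' \code{targetOddsRatio = Inf} returns a subset of the enriched genes.
#'
#' @param truth a \code{\link{SyntheticTruth}} with planted enriched genes
#' @param universe character vector of gene ids
#' @param targetOddsRatio positive real or \code{Inf}
#' @param size list size
#' @param seed integer seed
#' @return character vector of gene ids
#' @export
generateGeneList <- function(truth, universe, targetOddsRatio = 1,
                             size, seed = 1L) {
    enriched <- intersect(unique(unlist(truth@enrichedGenes)), universe)
    withr::with_seed(as.integer(seed), {
        if (is.infinite(targetOddsRatio)) {
            if (size > length(enriched))
                stop("size exceeds the planted enriched set at infinite odds ratio")
            return(sort(sample(enriched, size)))
        }
        w <- ifelse(universe %in% enriched, targetOddsRatio, 1)
        sort(sample(universe, size, prob = w))
    })
}

#' Generate a complete synthetic cohort
#'
#' Runs every generator with stage-specific seeds derived from
#' \code{cfg@seed} and merges the planted truth.
#'
#' @param cfg a \code{\link{CohortConfig}}
#' @param nNovelTars,nNovelExons,nNoise reconstructed-transcript planting,
#'   see \code{\link{generateReconstructedTranscripts}}
#' @return list with \code{annotation}, \code{cassetteExons},
#'   \code{expression} (\code{TissueExpression}), \code{events}
#'   (\code{SpliceEventSet}), \code{reconstructed} (\code{TranscriptSet})
#'   and \code{truth} (\code{SyntheticTruth})
#' @export
simulateCohort <- function(cfg, nNovelTars = 5L, nNovelExons = 5L,
                           nNoise = 10L) {
    annOut <- generateAnnotation(cfg)
    exprOut <- generateExpression(cfg, annOut$annotation)
    jcOut <- generateJunctionCounts(cfg, annOut$cassetteExons)
    recOut <- generateReconstructedTranscripts(cfg, annOut$annotation,
        nNovelTars = nNovelTars, nNovelExons = nNovelExons, nNoise = nNoise)
    truth <- exprOut$truth
    truth@truePsi <- jcOut$truePsi
    truth@shiftedExons <- jcOut$shiftedExons
    truth@novelTars <- recOut$novelTars
    truth@novelExons <- recOut$novelExons
    truth@knownCopies <- recOut$knownCopies
    truth@noiseTranscripts <- recOut$noiseTranscripts
    list(annotation = annOut$annotation,
         cassetteExons = annOut$cassetteExons,
         expression = exprOut$expression,
         events = jcOut$events,
         reconstructed = recOut$transcripts,
         truth = truth)
}
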