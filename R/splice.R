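#' @include AllClasses.R AllGenerics.R
NULL

# normalise a (UJC, DJC, SJC) triple given as vector or list
.asTriple <- function(x) {
    x <- unlist(x, use.names = FALSE)
    if (length(x) != 3L)
        stop("expected a (UJC, DJC, SJC) triple")
    if (any(x < 0))
        stop("junction counts must be non-negative")
    x
}

#' Exon inclusion level from junction counts
#'
#' The inclusion support of a cassette exon is I = (UJC + DJC)/2, the mean
#' of its two inclusion junctions (each included transcript copy generates
#' both junctions, so averaging puts inclusion and skipping on the same
#' per-transcript scale); the skipping support is S = SJC. The inclusion
#' level is PSI = I/(I + S), undefined (NA, never 0) when no informative
#' read was seen.
#'
#' All arguments are vectorised.
#'
#' @param ujc,djc,sjc non-negative junction read counts
#' @return data.frame with \code{I}, \code{S}, \code{informativeTotal}
#'   (I + S) and \code{psi}
#' @examples
#' estimatePsi(5, 15, 10)$psi   # I = 10, PSI = 0.5
#' estimatePsi(0, 0, 0)$psi    # NA
#' @export
estimatePsi <- function(ujc, djc, sjc) {
    if (any(c(ujc, djc, sjc) < 0))
        stop("junction counts must be non-negative")
    I <- (ujc + djc) / 2
    S <- sjc
    tot <- I + S
    data.frame(I = I, S = S, informativeTotal = tot,
               psi = ifelse(tot > 0, I / tot, NA_real_))
}

#' Pool junction counts over a tissue subset
#'
#' Element-wise sum of UJC, DJC and SJC across the subset, per event — the
#' pre-step for comparing one tissue against a pooled background panel.
#'
#' @param x a \code{\link{SpliceEventSet}}
#' @param tissues non-empty character vector of tissue (column) names
#' @return data.frame with one row per event: \code{ujc}, \code{djc},
#'   \code{sjc}
#' @export
poolConditions <- function(x, tissues) {
    if (!length(tissues))
        stop("tissue subset must be non-empty")
    bad <- setdiff(tissues, colnames(x))
    if (length(bad))
        stop("unknown tissue(s): ", paste(bad, collapse = ", "))
    data.frame(
        ujc = rowSums(assay(x, "ujc")[, tissues, drop = FALSE]),
        djc = rowSums(assay(x, "djc")[, tissues, drop = FALSE]),
        sjc = rowSums(assay(x, "sjc")[, tissues, drop = FALSE]),
        row.names = rownames(x))
}

# round half up: I is integer or half-integer
.roundHalfUp <- function(x) floor(x + 0.5)

# (k, n) binomial summary of a junction triple: k = round(I), n = k + S
.knOf <- function(counts) {
    v <- .asTriple(counts)
    k <- .roundHalfUp((v[1] + v[2]) / 2)
    c(k = k, n = k + v[3])
}

# Posterior-mass machinery. With a uniform(0,1) prior and k successes in n
# trials the posterior of PSI is Beta(k+1, n-k+1). The grid integration
# uses midpoint cells in one coordinate and the exact Beta CDF in the
# other, symmetrised over the two orderings so the result is exactly
# symmetric in its arguments.
.gridCache <- function(gridStep) {
    G <- round(1 / gridStep)
    list(G = G, bounds = (0:G) * gridStep,
         mid = (seq_len(G) - 0.5) * gridStep)
}

# per-cell posterior mass of Beta(k+1, n-k+1)
.cellMass <- function(k, n, grid)
    diff(pbeta(grid$bounds, k + 1, n - k + 1))

# P(|v - u| > c) under Beta(k+1, n-k+1) for v, at each grid midpoint u
.bandComplement <- function(k, n, grid, c)
    pbeta(grid$mid - c, k + 1, n - k + 1) +
        (1 - pbeta(grid$mid + c, k + 1, n - k + 1))

.postProbKN <- function(k1, n1, k2, n2, c, grid) {
    s12 <- sum(.cellMass(k1, n1, grid) * .bandComplement(k2, n2, grid, c))
    s21 <- sum(.cellMass(k2, n2, grid) * .bandComplement(k1, n1, grid, c))
    (s12 + s21) / 2
}

#' Posterior probability of a splicing difference exceeding c
#'
#' Bayesian evidence that two conditions differ in inclusion level by more
#' than \code{c}: with independent uniform(0,1) priors on (PSI1, PSI2) and,
#' per condition, a binomial likelihood of round(I) inclusion successes in
#' round(I) + S informative trials, returns the posterior mass of the
#' region |PSI1 - PSI2| > c, computed by grid integration at resolution
#' \code{gridStep}. A condition with no informative reads contributes its
#' prior, so two empty conditions give the prior band-complement area
#' 1 - (2c - c^2).
#'
#' @param counts1,counts2 (UJC, DJC, SJC) triples
#' @param c difference threshold in (0,1); default 0.1 (a 10-point
#'   inclusion shift)
#' @param gridStep integration resolution (default 0.001)
#' @return posterior probability in [0, 1]
#' @examples
#' posteriorDiffProb(c(0, 0, 0), c(0, 0, 0))        # prior: 0.81
#' posteriorDiffProb(c(100, 100, 0), c(0, 0, 100))  # ~1
#' @export
posteriorDiffProb <- function(counts1, counts2, c = 0.1, gridStep = 0.001) {
    stopifnot(c > 0, c < 1)
    kn1 <- .knOf(counts1); kn2 <- .knOf(counts2)
    grid <- .gridCache(gridStep)
    .postProbKN(kn1["k"], kn1["n"], kn2["k"], kn2["n"], c, grid)
}

# Vectorised statistic over replicate (k1, k2) pairs at fixed (n1, n2),
# reusing cached per-(k, n) grid vectors. cache is an environment keyed
# "k/n" holding list(w = cell masses, g = band complement).
.knVectors <- function(k, n, c, grid, cache) {
    key <- paste0(k, "/", n)
    hit <- cache[[key]]
    if (is.null(hit)) {
        hit <- list(w = .cellMass(k, n, grid),
                    g = .bandComplement(k, n, grid, c))
        cache[[key]] <- hit
    }
    hit
}

.postProbPairs <- function(k1v, n1, k2v, n2, c, grid, cache) {
    u1 <- sort(unique(k1v)); u2 <- sort(unique(k2v))
    V1 <- lapply(u1, .knVectors, n = n1, c = c, grid = grid, cache = cache)
    V2 <- lapply(u2, .knVectors, n = n2, c = c, grid = grid, cache = cache)
    W1 <- do.call(rbind, lapply(V1, `[[`, "w"))
    G1 <- do.call(rbind, lapply(V1, `[[`, "g"))
    W2 <- do.call(rbind, lapply(V2, `[[`, "w"))
    G2 <- do.call(rbind, lapply(V2, `[[`, "g"))
    statTab <- (W1 %*% t(G2) + G1 %*% t(W2)) / 2   # u1 x u2
    statTab[cbind(match(k1v, u1), match(k2v, u2))]
}

#' Bootstrap p-value for differential splicing
#'
#' Frequentist companion of \code{\link{posteriorDiffProb}}: a parametric
#' bootstrap under the boundary null |PSI1 - PSI2| <= c. The constrained
#' maximum-likelihood pair (PSI1*, PSI2*) is fitted subject to the
#' constraint, B replicate count pairs are simulated at the observed
#' informative totals, and
#' p = (1 + #\{replicates with statistic >= observed\}) / (B + 1).
#'
#' @inheritParams posteriorDiffProb
#' @param B bootstrap replicates (>= 100; default 1000)
#' @param seed optional integer seed for the replicate draws
#' @return list with \code{pValue}, \code{stat} (the observed posterior
#'   probability), and \code{mle} (the constrained (PSI1*, PSI2*))
#' @export
diffSplicingPvalue <- function(counts1, counts2, c = 0.1, B = 1000,
                               seed = NULL, gridStep = 0.001) {
    stopifnot(B >= 100)
    kn1 <- .knOf(counts1); kn2 <- .knOf(counts2)
    if (kn1["n"] == 0 && kn2["n"] == 0) {
        message("no informative reads in either condition; p = 1")
        return(list(pValue = 1, stat = NA_real_, mle = c(NA_real_, NA_real_)))
    }
    grid <- .gridCache(gridStep)
    cache <- new.env(parent = emptyenv())
    obs <- .postProbKN(kn1["k"], kn1["n"], kn2["k"], kn2["n"], c, grid)
    mle <- .constrainedMle(kn1["k"], kn1["n"], kn2["k"], kn2["n"], c)
    draw <- function() {
        k1s <- rbinom(B, kn1["n"], mle[1])
        k2s <- rbinom(B, kn2["n"], mle[2])
        .postProbPairs(k1s, kn1["n"], k2s, kn2["n"], c, grid, cache)
    }
    stats <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    list(pValue = (1 + sum(stats >= obs)) / (B + 1), stat = obs, mle = mle)
}

# maximum likelihood (p1, p2) under |p1 - p2| <= c for two binomials
.constrainedMle <- function(k1, n1, k2, n2, c) {
    p1 <- if (n1 > 0) k1 / n1 else NA_real_
    p2 <- if (n2 > 0) k2 / n2 else NA_real_
    if (is.na(p1)) p1 <- p2
    if (is.na(p2)) p2 <- p1
    if (abs(p1 - p2) <= c)
        return(c(p1, p2))
    # active constraint: the optimum sits on the nearer boundary
    sgn <- sign(p1 - p2)    # p1 = p2 + sgn * c
    ll <- function(q) {     # q = p2
        p <- q + sgn * c
        stats::dbinom(k1, n1, p, log = TRUE) +
            stats::dbinom(k2, n2, q, log = TRUE)
    }
    lo <- max(1e-9, -sgn * c); hi <- min(1 - 1e-9, 1 - sgn * c)
    opt <- optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-9)
    c(opt$maximum + sgn * c, opt$maximum)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment; a thin, name-stable wrapper
#' over \code{stats::p.adjust(..., "BH")} that tolerates empty input.
#'
#' @param p numeric vector of p-values in [0, 1]
#' @return q-values, same length and names as \code{p}
#' @export
fdrAdjust <- function(p) {
    stopifnot(all(p >= 0 & p <= 1))
    if (!length(p))
        return(numeric(0))
    p.adjust(p, method = "BH")
}

#' Call differentially spliced cassette exons between two conditions
#'
#' Pools junction counts within each condition, excludes events with fewer
#' than \code{minInformative} informative reads (I + S) in either condition
#' (reported as untested), computes the posterior probability of
#' |PSI1 - PSI2| > c and a bootstrap p-value per tested event, adjusts with
#' Benjamini-Hochberg, and calls an exon differential when the observed
#' |PSI1 - PSI2| exceeds \code{c} and its FDR is below \code{fdrCutoff}.
#'
#' @param x a \code{\link{SpliceEventSet}}
#' @param condition1,condition2 disjoint tissue-name vectors; multi-tissue
#'   conditions are pooled before estimation
#' @param c inclusion-difference threshold (default 0.1)
#' @param fdrCutoff FDR threshold for calling (default 0.1)
#' @param minInformative minimum informative reads per condition
#'   (default 10)
#' @param B bootstrap replicates per event (default 1000)
#' @param seed integer seed for the bootstrap
#' @param gridStep posterior integration resolution
#' @return list with \code{results} (a \code{DataFrame}: event, gene, psi1,
#'   psi2, delta, posteriorProb, pValue, fdr, tested, called) and
#'   \code{summary} (nEvents, nTested, nCalled, nGenesCalled,
#'   pctTestedCalled)
#' @export
callDifferentialExons <- function(x, condition1, condition2, c = 0.1,
        fdrCutoff = 0.1, minInformative = 10, B = 1000, seed = 1L,
        gridStep = 0.001) {
    if (length(intersect(condition1, condition2)))
        stop("conditions must be disjoint")
    c1 <- poolConditions(x, condition1)
    c2 <- poolConditions(x, condition2)
    e1 <- estimatePsi(c1$ujc, c1$djc, c1$sjc)
    e2 <- estimatePsi(c2$ujc, c2$djc, c2$sjc)
    tested <- e1$informativeTotal >= minInformative &
        e2$informativeTotal >= minInformative
    delta <- abs(e1$psi - e2$psi)
    res <- DataFrame(event_id = rownames(x),
                     gene_id = mcols(rowRanges(x))$gene_id,
                     psi1 = e1$psi, psi2 = e2$psi, delta = delta,
                     posteriorProb = NA_real_, pValue = NA_real_,
                     fdr = NA_real_, tested = tested, called = FALSE,
                     row.names = NULL)
    idx <- which(tested)
    if (length(idx)) {
        grid <- .gridCache(gridStep)
        cache <- new.env(parent = emptyenv())
        pv <- post <- numeric(length(idx))
        seeds <- seed + seq_along(idx)        # per-event replicate seeds
        for (j in seq_along(idx)) {
            i <- idx[j]
            t1 <- c(c1$ujc[i], c1$djc[i], c1$sjc[i])
            t2 <- c(c2$ujc[i], c2$djc[i], c2$sjc[i])
            kn1 <- .knOf(t1); kn2 <- .knOf(t2)
            post[j] <- .postProbKN(kn1["k"], kn1["n"], kn2["k"], kn2["n"],
                                   c, grid)
            mle <- .constrainedMle(kn1["k"], kn1["n"], kn2["k"], kn2["n"], c)
            stats <- withr::with_seed(seeds[j], {
                k1s <- rbinom(B, kn1["n"], mle[1])
                k2s <- rbinom(B, kn2["n"], mle[2])
                .postProbPairs(k1s, kn1["n"], k2s, kn2["n"], c, grid, cache)
            })
            pv[j] <- (1 + sum(stats >= post[j])) / (B + 1)
        }
        res$posteriorProb[idx] <- post
        res$pValue[idx] <- pv
        res$fdr[idx] <- fdrAdjust(pv)
        res$called[idx] <- delta[idx] > c & res$fdr[idx] < fdrCutoff
    }
    called <- res$called & !is.na(res$called)
    list(results = res,
         summary = list(
             nEvents = nrow(res), nTested = sum(tested),
             nCalled = sum(called),
             nGenesCalled = length(unique(res$gene_id[called])),
             pctTestedCalled = if (sum(tested) > 0)
                 100 * sum(called) / sum(tested) else NA_real_))
}
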