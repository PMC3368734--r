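#' @include AllClasses.R
NULL

#' Build a 2x2 overlap table for a query set against an annotation list
#'
#' Exact set arithmetic within a stated gene universe: a = |query n list|,
#' b = |query \\ list|, c = |list \\ query|, d = the rest of the universe.
#' The universe is always an explicit input, never inferred — the
#' appropriate background differs between analyses (all annotated genes,
#' expressed genes, tested genes, ...). List members outside the universe
#' are dropped with a notice before counting.
#'
#' @param query character vector of gene ids, must lie within the universe
#' @param annotationList character vector of gene ids (the external list)
#' @param universe non-empty character vector of gene ids
#' @return one-row data.frame: \code{a}, \code{b}, \code{c}, \code{d},
#'   \code{queryOverlapProp} (a/|query|), \code{listOverlapProp}
#'   (a/|list n universe|)
#' @export
buildOverlapTable <- function(query, annotationList, universe) {
    universe <- unique(universe)
    if (!length(universe))
        stop("universe must be non-empty")
    query <- unique(query)
    if (!all(query %in% universe))
        stop("query contains ids outside the universe: ",
             paste(utils::head(setdiff(query, universe), 3), collapse = ", "))
    annotationList <- unique(annotationList)
    dropped <- sum(!annotationList %in% universe)
    if (dropped > 0)
        message("dropping ", dropped, " list id(s) outside the universe")
    lst <- intersect(annotationList, universe)
    a <- length(intersect(query, lst))
    b <- length(setdiff(query, lst))
    cc <- length(setdiff(lst, query))
    d <- length(universe) - a - b - cc
    data.frame(a = a, b = b, c = cc, d = d,
               queryOverlapProp = if (length(query)) a / length(query)
                                  else NA_real_,
               listOverlapProp = if (length(lst)) a / length(lst)
                                 else NA_real_)
}

#' Fisher's exact test on a 2x2 overlap table
#'
#' Computed from the hypergeometric distribution conditioned on the table
#' margins. \code{alternative = "greater"} (the enrichment question, the
#' default) is the upper tail P[X >= a]; \code{"two.sided"} sums the
#' probabilities of all tables at the observed margins whose point
#' probability does not exceed that of the observed table. The odds ratio
#' is the sample odds ratio a*d/(b*c), reported as \code{Inf} when
#' b*c = 0 and a*d > 0.
#'
#' @param table a one-row data.frame/list with \code{a}, \code{b},
#'   \code{c}, \code{d} (as from \code{\link{buildOverlapTable}}), or a
#'   numeric vector (a, b, c, d)
#' @param alternative \code{"greater"}, \code{"less"} or
#'   \code{"two.sided"}
#' @return list with \code{oddsRatio} and \code{pValue}
#' @examples
#' fisherExact(c(3, 1, 1, 3), alternative = "two.sided")$pValue  # 34/70
#' @export
fisherExact <- function(table, alternative = c("greater", "two.sided",
                                               "less")) {
    alternative <- match.arg(alternative)
    v <- if (is.data.frame(table) || is.list(table))
        c(table$a, table$b, table$c, table$d) else as.numeric(table)
    stopifnot(length(v) == 4, all(v >= 0), all(v == round(v)))
    a <- v[1]; b <- v[2]; cc <- v[3]; d <- v[4]
    m <- a + cc          # list size
    n <- b + d           # universe minus list
    k <- a + b           # query size
    support <- max(0, k - n):min(k, m)
    pr <- stats::dhyper(support, m, n, k)
    pObs <- stats::dhyper(a, m, n, k)
    p <- switch(alternative,
        greater = sum(pr[support >= a]),
        less = sum(pr[support <= a]),
        two.sided = sum(pr[pr <= pObs * (1 + 1e-7)]))
    or <- if (b * cc == 0) {
        if (a * d > 0) Inf else NA_real_
    } else a * d / (b * cc)
    list(oddsRatio = or, pValue = min(1, p))
}
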