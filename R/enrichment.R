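# Overlap and reciprocity significance tests for comparing predictions
# with experimental multicopy-suppression sets.

#' Upper-tail hypergeometric overlap p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of drawing at
#' least \code{k} of the \code{K} experimental positives when sampling
#' \code{n} predictions from a population of \code{N}, computed in log
#' space for numerical safety.
#'
#' @param N population size.
#' @param K experimental positives in the population.
#' @param n predictions drawn.
#' @param k observed overlap.
#' @return p-value in (0, 1].
#' @export
#' @examples
#' hypergeomOverlapPvalue(10, 5, 5, 5)   # 1 / choose(10, 5)
hypergeomOverlapPvalue <- function(N, K, n, k) {
    if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(n, K))
        stop("invalid hypergeometric parameters: need K, n <= N and ",
             "k <= min(n, K)")
    if (k == 0) return(1)
    exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE,
                      log.p = TRUE))
}

#' Reciprocal fraction of a prediction set
#'
#' Fraction of distinct ordered (target, replacer) pairs whose reverse
#' pair is also predicted; the baseline reciprocity rate.
#'
#' @param pairs pair data.frame.
#' @return Fraction in \[0, 1\] (0 for an empty set).
#' @export
reciprocalRate <- function(pairs) {
    if (!nrow(pairs)) return(0)
    fwd <- unique(paste(pairs$target_gene, pairs$replacer_gene,
                        sep = "\r"))
    parts <- strsplit(fwd, "\r", fixed = TRUE)
    rev <- vapply(parts, function(p) paste(p[2L], p[1L], sep = "\r"), "")
    mean(fwd %in% rev)
}

#' Probability that m independent pairs are all reciprocal
#'
#' Under the null that every pair is reciprocal with the same
#' probability \code{r}, P(all m reciprocal) = r^m. When \code{r} is
#' not supplied it is estimated as the reciprocal fraction of
#' \code{pairs} (the full prediction set).
#'
#' @param m number of observed reciprocal pairs.
#' @param r baseline reciprocity rate in (0, 1].
#' @param pairs pair data.frame used to estimate \code{r} when missing.
#' @return p-value r^m.
#' @export
reciprocityPvalue <- function(m, r = NULL, pairs = NULL) {
    if (is.null(r)) {
        if (is.null(pairs))
            stop("supply either r or a prediction set to estimate it from")
        r <- reciprocalRate(pairs)
    }
    if (r <= 0) stop("baseline reciprocity rate must be > 0")
    if (r > 1) stop("baseline reciprocity rate must be <= 1")
    r ^ m
}

#' Overlap test between predicted and experimental pair sets
#'
#' Counts the overlap between two (target, replacer) pair tables and
#' computes the upper-tail hypergeometric p-value. The drawing unit is
#' either unordered gene pairs or replacer genes (the published
#' analyses are ambiguous on the unit, so both are supported).
#'
#' @param predicted,experimental pair data.frames.
#' @param N background population size (e.g. number of candidate
#'   replacers, or of candidate pairs).
#' @param unit "pairs" (unordered gene pairs) or "genes" (replacer
#'   genes).
#' @return list: N, K, n, k, p_value.
#' @export
overlapTest <- function(predicted, experimental, N,
                        unit = c("pairs", "genes")) {
    unit <- match.arg(unit)
    keyFun <- if (unit == "pairs") {
        function(p) unique(vapply(seq_len(nrow(p)), function(i)
            paste(sort(c(p$target_gene[i], p$replacer_gene[i])),
                  collapse = "\r"), ""))
    } else {
        function(p) unique(p$replacer_gene)
    }
    a <- keyFun(predicted)
    b <- keyFun(experimental)
    k <- length(intersect(a, b))
    list(N = N, K = length(b), n = length(a), k = k,
         p_value = hypergeomOverlapPvalue(N, length(b), length(a), k))
}
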