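#' One-sided Fisher's exact test on a 2x2 table
#'
#' Upper-tail (enrichment) exact test: the probability, given the margins,
#' of observing at least \code{a} in the top-left cell. This is the test
#' used for contrasts such as the fraction of LTR-promoter vlincRNAs whose
#' expression maximum falls in a cancer sample versus the nonLTR fraction.
#'
#' @param a,b,c,d non-negative integer cell counts, rows = category,
#'   columns = outcome.
#' @param alternative \code{"greater"} (default) or \code{"two.sided"}.
#' @return the p-value.
#' @examples
#' fisherOneSided(406, 205, 614, 477)   # ~2.3e-5
#' @export
fisherOneSided <- function(a, b, c, d,
                           alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b + c + d > 0)
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab, alternative = alternative)$p.value
}

#' Hypergeometric enrichment (upper tail) with expected count
#'
#' P(X >= k) for drawing \code{n} items without replacement from a
#' population of \code{N} containing \code{K} successes, plus the expected
#' success count \code{n * K / N}.
#'
#' @param N population size.
#' @param K successes in the population.
#' @param n draws.
#' @param k observed successes among the draws.
#' @return list with \code{p} and \code{expected}.
#' @examples
#' hypergeomEnrichment(833, 332, 100, 86)  # p ~ 3.9e-24, expected ~ 40
#' @export
hypergeomEnrichment <- function(N, K, n, k) {
  stopifnot(N >= 0, K >= 0, K <= N, n >= 0, n <= N)
  if (k < 0 || k > min(n, K))
    stop("impossible observed count k = ", k)
  list(p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
       expected = n * K / N)
}

#' Binomial upper-tail probability
#'
#' P(X >= k) for X ~ Binomial(n, p); the upper-bound overlap significance
#' used by the intergenic-corrected interval-overlap test.
#'
#' @param n trials.
#' @param k successes.
#' @param p success probability.
#' @return the tail probability.
#' @examples
#' binomialUpperTail(1542, 15, 0.0043)  # ~0.0034
#' @export
binomialUpperTail <- function(n, k, p) {
  stopifnot(n >= 0, k >= 0, k <= n, p >= 0, p <= 1)
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Spearman rank correlation with a not-computable sentinel
#'
#' Average-rank (tie-sharing) Spearman correlation. A constant vector has
#' no rank variance, so the correlation is undefined; \code{NA} is returned
#' and downstream median/distribution summaries drop such values. This is
#' deliberate: all-zero expression rows are common in sparse data.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in [-1, 1], or \code{NA_real_} when not computable.
#' @export
spearmanRho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Row-wise Spearman correlations against one reference vector
#'
#' Vectorized helper: Spearman rho of each row of \code{m} against
#' \code{y}, with the same not-computable sentinel as
#' \code{\link{spearmanRho}}.
#'
#' @param m numeric matrix (features x samples).
#' @param y numeric vector of length \code{ncol(m)}.
#' @return numeric vector of correlations (NA where undefined).
#' @export
spearmanRows <- function(m, y) {
  stopifnot(ncol(m) == length(y))
  if (stats::sd(y) == 0) return(rep(NA_real_, nrow(m)))
  ry <- rank(y)
  rm <- t(apply(m, 1L, rank))
  sds <- apply(rm, 1L, stats::sd)
  out <- rep(NA_real_, nrow(m))
  ok <- sds > 0
  if (any(ok)) {
    rm <- rm[ok, , drop = FALSE]
    out[ok] <- as.numeric(stats::cor(t(rm), ry, method = "pearson"))
  }
  out
}

#' One-sided Kolmogorov-Smirnov test
#'
#' @param a,b numeric samples.
#' @param alternative \code{"a_greater"}: a is stochastically larger than b;
#'   \code{"a_less"}: a is stochastically smaller.
#' @return list with \code{statistic} and \code{p}.
#' @export
ksOneSided <- function(a, b, alternative = c("a_greater", "a_less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) > 0, length(b) > 0)
  # ks.test alternative "less": CDF of x lies below that of y  => x larger
  alt <- if (alternative == "a_greater") "less" else "greater"
  kt <- suppressWarnings(stats::ks.test(a, b, alternative = alt))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

#' One-sided Mann-Whitney-Wilcoxon test
#'
#' @param a,b numeric samples.
#' @param alternative \code{"a_greater"} or \code{"a_less"}.
#' @return list with \code{statistic} and \code{p}.
#' @export
mwwOneSided <- function(a, b, alternative = c("a_greater", "a_less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) > 0, length(b) > 0)
  alt <- if (alternative == "a_greater") "greater" else "less"
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = alt))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Monotone step-up adjustment; preserves the ordering of the raw p-values.
#'
#' @param pvals numeric vector of raw p-values (possibly empty).
#' @return adjusted p-values, same length.
#' @export
bhAdjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  stats::p.adjust(pvals, method = "BH")
}

#' Empirical permutation p-value
#'
#' Uses the add-one estimator p = (1 + #\{null >= observed\}) / (1 + n),
#' which can never return zero: an observed statistic exceeding all 1000
#' null draws reports p = 1/1001, i.e. the reproducible "< 0.001".
#'
#' @param observed observed statistic.
#' @param nullDraws numeric vector of null-statistic draws (non-empty).
#' @return the empirical p-value.
#' @export
empiricalPermP <- function(observed, nullDraws) {
  if (!length(nullDraws)) stop("empty null distribution")
  (1 + sum(nullDraws >= observed)) / (1 + length(nullDraws))
}
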