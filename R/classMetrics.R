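#' Ratio of maximum expression in cancer versus normal (RMECN)
#'
#' For each promoter-assigned vlincRNA, the maximum expression over cancer
#' samples divided by the maximum over normal samples; stem and
#' immortalized samples enter neither maximum. The statistic targets
#' highly cell-type-specific transcripts for which median- or
#' average-based tumour/normal ratios carry no signal. VlincRNAs whose
#' normal maximum is zero have an undefined ratio and are excluded from
#' the medians (their count is reported).
#'
#' @param expr \code{\link{VlincExperiment}} or matrix with feature rownames.
#' @param samples data.frame with \code{sample_id} and \code{class}
#'   (normal/cancer/stem/immortalized) matching the expression columns.
#' @param annotation \code{\link{annotateVlincs}} output (vlinc_id +
#'   category); only categories LTR and nonLTR enter.
#' @return list: \code{perVlinc} (data.frame vlinc_id, category,
#'   max_cancer, max_normal, rmecn), \code{medians} (named LTR/nonLTR),
#'   \code{ratio} (median LTR / median nonLTR), \code{n_undefined}.
#' @export
rmecn <- function(expr, samples, annotation) {
  m <- if (is(expr, "VlincExperiment")) rpkmValues(expr) else expr
  stopifnot(all(samples$sample_id == colnames(m)))
  cancerCols <- samples$class == "cancer"
  normalCols <- samples$class == "normal"
  if (!any(cancerCols) || !any(normalCols))
    stop("need at least one cancer and one normal sample")
  ann <- annotation[annotation$category %in% c("LTR", "nonLTR"), ]
  ann <- ann[ann$vlinc_id %in% rownames(m), ]
  sub <- m[ann$vlinc_id, , drop = FALSE]
  maxC <- apply(sub[, cancerCols, drop = FALSE], 1L, max)
  maxN <- apply(sub[, normalCols, drop = FALSE], 1L, max)
  if (all(maxN == 0)) stop("degenerate design: all normal maxima are zero")
  ok <- maxN > 0
  per <- data.frame(vlinc_id = ann$vlinc_id, category = ann$category,
                    max_cancer = maxC, max_normal = maxN,
                    rmecn = ifelse(ok, maxC / maxN, NA_real_),
                    stringsAsFactors = FALSE, row.names = NULL)
  med <- tapply(per$rmecn[ok], per$category[ok], stats::median)
  medians <- c(LTR = unname(med["LTR"]), nonLTR = unname(med["nonLTR"]))
  list(perVlinc = per, medians = medians,
       ratio = unname(medians["LTR"] / medians["nonLTR"]),
       n_undefined = sum(!ok))
}

#' Label-permutation test for the LTR/nonLTR RMECN contrast
#'
#' The statistic is median-RMECN(LTR) / median-RMECN(nonLTR). Cancer and
#' normal labels are permuted among the cancer+normal samples (class sizes
#' preserved), the statistic recomputed each time, and the empirical
#' p-value estimated with the add-one rule -- a statistic above every null
#' draw reports 1/(nPerm + 1).
#'
#' @param expr,samples,annotation as in \code{\link{rmecn}}.
#' @param nPerm number of permutations (a warning below 100).
#' @param seed integer seed for the permutation stream.
#' @return list: \code{observed}, \code{p}, \code{nullDraws}.
#' @export
labelPermutationTest <- function(expr, samples, annotation,
                                 nPerm = 1000L, seed = 1L) {
  if (nPerm < 100L) warning("fewer than 100 permutations is unreliable")
  m <- if (is(expr, "VlincExperiment")) rpkmValues(expr) else expr
  ann <- annotation[annotation$category %in% c("LTR", "nonLTR"), ]
  ann <- ann[ann$vlinc_id %in% rownames(m), ]
  sub <- m[ann$vlinc_id, , drop = FALSE]
  isLtr <- ann$category == "LTR"
  cn <- which(samples$class %in% c("cancer", "normal"))
  nCancer <- sum(samples$class == "cancer")
  stat <- function(cancerIdx) {
    normalIdx <- setdiff(cn, cancerIdx)
    maxC <- apply(sub[, cancerIdx, drop = FALSE], 1L, max)
    maxN <- apply(sub[, normalIdx, drop = FALSE], 1L, max)
    ok <- maxN > 0
    r <- maxC[ok] / maxN[ok]
    stats::median(r[isLtr[ok]]) / stats::median(r[!isLtr[ok]])
  }
  observed <- stat(which(samples$class == "cancer"))
  set.seed(seed)
  nullDraws <- vapply(seq_len(nPerm), function(i)
    stat(sample(cn, nCancer)), 0)
  list(observed = observed, p = empiricalPermP(observed, nullDraws),
       nullDraws = nullDraws)
}

#' Where does each vlincRNA reach its expression maximum?
#'
#' For each promoter-assigned vlincRNA, the class of the sample attaining
#' its global maximum (ties broken by the first sample index). Builds the
#' 2x2 table category x (max-in-cancer vs not) and its one-sided Fisher
#' p-value; vlincRNAs peaking in stem or immortalized samples can be
#' excluded first.
#'
#' @param expr,samples,annotation as in \code{\link{rmecn}}.
#' @param excludeStemImmortalized drop vlincRNAs whose maximum falls in a
#'   stem or immortalized sample (default FALSE).
#' @return list: \code{table} (2x2 matrix), \code{p}, \code{perVlinc}.
#' @export
maxLocationCounts <- function(expr, samples, annotation,
                              excludeStemImmortalized = FALSE) {
  m <- if (is(expr, "VlincExperiment")) rpkmValues(expr) else expr
  ann <- annotation[annotation$category %in% c("LTR", "nonLTR"), ]
  ann <- ann[ann$vlinc_id %in% rownames(m), ]
  sub <- m[ann$vlinc_id, , drop = FALSE]
  if (all(apply(sub, 1L, function(r) length(unique(r))) == 1L))
    warning("all-constant expression: every maximum is a tie")
  peak <- apply(sub, 1L, which.max)   # first index on ties
  peakClass <- samples$class[peak]
  keep <- rep(TRUE, nrow(ann))
  if (excludeStemImmortalized)
    keep <- !(peakClass %in% c("stem", "immortalized"))
  per <- data.frame(vlinc_id = ann$vlinc_id[keep],
                    category = ann$category[keep],
                    peak_class = peakClass[keep], stringsAsFactors = FALSE)
  a <- sum(per$category == "LTR" & per$peak_class == "cancer")
  b <- sum(per$category == "LTR" & per$peak_class != "cancer")
  c_ <- sum(per$category == "nonLTR" & per$peak_class == "cancer")
  d <- sum(per$category == "nonLTR" & per$peak_class != "cancer")
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                dimnames = list(c("LTR", "nonLTR"),
                                c("max_in_cancer", "not")))
  list(table = tab, p = fisherOneSided(a, b, c_, d), perVlinc = per)
}

#' Per-sample tag-mass fractions of vlincRNA sets
#'
#' For each sample and each named vlincRNA set, the fraction of tags whose
#' 5' ends fall in the set's masked bodies relative to (i) the sample's
#' informative reads and (ii) the tags in all vlincRNA masked bodies.
#'
#' @param tagsets named list of \code{\link{TagSet}}.
#' @param vlincSets named list of stranded \code{GRanges} (e.g. distal LTR
#'   and distal nonLTR vlincRNAs).
#' @param bundle an \code{\link{AnnotationBundle}} supplying the masks and
#'   the full vlincRNA complement.
#' @return data.frame: sample_id, set, tags_in_set,
#'   frac_informative, frac_vlinc_mass.
#' @export
massFractions <- function(tagsets, vlincSets, bundle) {
  masks <- c(granges(unlist(geneExons(bundle))),
             granges(rrnaRepeats(bundle)))
  maskedSet <- lapply(vlincSets, function(v) subtractMasks(v, masks, "any"))
  allMasked <- subtractMasks(vlincRanges(bundle), masks, "any")
  rows <- list()
  for (s in names(tagsets)) {
    ts <- tagsets[[s]]
    denomAll <- countTags(ts, allMasked)
    for (nm in names(maskedSet)) {
      inSet <- countTags(ts, maskedSet[[nm]])
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, set = nm, tags_in_set = inSet,
        frac_informative = inSet / informativeReads(ts),
        frac_vlinc_mass = if (denomAll > 0) inSet / denomAll else 0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Class enrichment in the top-N samples by fraction
#'
#' Ranks samples by a fraction (descending, ties broken by sample id) and
#' tests whether the focal class is over-represented among the top N with
#' the hypergeometric upper tail.
#'
#' @param fractions named numeric vector (names = sample ids).
#' @param samples sample table (sample_id, class).
#' @param n top-list size (default 100).
#' @param class focal class (default "cancer").
#' @return list: \code{k} (class members in top n), \code{p},
#'   \code{expected}.
#' @export
topNClassEnrichment <- function(fractions, samples, n = 100L,
                                class = "cancer") {
  stopifnot(n <= length(fractions))
  ord <- order(-fractions, names(fractions))
  top <- names(fractions)[ord][seq_len(n)]
  cls <- stats::setNames(samples$class, samples$sample_id)
  k <- sum(cls[top] == class)
  he <- hypergeomEnrichment(N = nrow(samples), K = sum(cls == class),
                            n = n, k = k)
  list(k = k, p = he$p, expected = he$expected)
}

#' Pairwise one-sided class comparisons of per-sample fractions
#'
#' For every ordered pair of sample classes, the one-sided
#' Mann-Whitney-Wilcoxon p-value that the first class's fractions are
#' larger; per-class medians are reported alongside.
#'
#' @param fractions named numeric vector (names = sample ids).
#' @param samples sample table (sample_id, class).
#' @return list: \code{p} (matrix class x class, row greater than column),
#'   \code{medians}.
#' @export
classFractionTests <- function(fractions, samples) {
  cls <- stats::setNames(samples$class, samples$sample_id)[names(fractions)]
  classes <- intersect(c("cancer", "normal", "stem", "immortalized"),
                       unique(cls))
  p <- matrix(NA_real_, length(classes), length(classes),
              dimnames = list(classes, classes))
  for (i in classes) for (j in setdiff(classes, i))
    p[i, j] <- mwwOneSided(fractions[cls == i], fractions[cls == j],
                           "a_greater")$p
  medians <- vapply(classes, function(cl)
    stats::median(fractions[cls == cl]), 0)
  list(p = p, medians = medians)
}

#' Trend test for a fraction along a differentiation time course
#'
#' Fits a simple linear regression of the fraction on the time index and
#' reports the overall regression F-test, one-sided for the decreasing
#' direction (p halved when the slope is negative). An increasing slope is
#' reported as direction "increase" with p = NA, the convention used when
#' a decline is the biological hypothesis.
#'
#' @param fractions numeric vector of per-time-point fractions.
#' @param timeIndex numeric time indices (same length).
#' @return list: \code{slope}, \code{direction}, \code{p} (NA when the
#'   trend increases).
#' @export
timecourseTrend <- function(fractions, timeIndex) {
  stopifnot(length(fractions) == length(timeIndex), length(fractions) >= 3)
  fit <- stats::lm(fractions ~ timeIndex)
  # a perfect fit triggers summary.lm's reliability warning; the zero-sigma
  # branch below handles that case explicitly
  sm <- suppressWarnings(summary(fit))
  slope <- stats::coef(fit)[["timeIndex"]]
  if (is.na(slope) || sm$sigma == 0) {
    # perfect fit: zero residual variance, F-test degenerates
    return(list(slope = slope,
                direction = if (slope < 0) "decrease" else "increase",
                p = if (slope < 0) 0 else NA_real_))
  }
  f <- sm$fstatistic
  pTwo <- stats::pf(f[["value"]], f[["numdf"]], f[["dendf"]],
                    lower.tail = FALSE)
  if (slope < 0) list(slope = slope, direction = "decrease", p = pTwo / 2)
  else if (slope == 0) list(slope = 0, direction = "flat", p = 1)
  else list(slope = slope, direction = "increase", p = NA_real_)
}
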