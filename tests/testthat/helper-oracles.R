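suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

# --- independent brute-force oracles -----------------------------------

# residual unmasked bases of [s, e] (1-based closed) under masks
oracleResidual <- function(s, e, maskS, maskE) {
  covered <- rep(FALSE, e - s + 1L)
  for (i in seq_along(maskS)) {
    lo <- max(s, maskS[i]); hi <- min(e, maskE[i])
    if (lo <= hi) covered[(lo - s + 1L):(hi - s + 1L)] <- TRUE
  }
  sum(!covered)
}

# per-base strand-specific union of intervals -> merged interval count and
# total covered bases per strand
oracleMerge <- function(chr, s, e, strand, genomeLen = 10000L) {
  out <- list()
  for (cc in unique(chr)) for (st in unique(strand[chr == cc])) {
    sel <- chr == cc & strand == st
    cov <- rep(FALSE, genomeLen)
    for (i in which(sel)) cov[s[i]:e[i]] <- TRUE
    r <- rle(cov)
    out[[paste(cc, st)]] <- list(
      n = sum(r$values),
      bases = sum(cov),
      starts = cumsum(c(1L, r$lengths))[-(length(r$lengths) + 1L)][r$values])
  }
  out
}

# any insulator wholly inside the open gap between two intervals?
oracleSeparated <- function(aS, aE, bS, bE, insS, insE) {
  gapLo <- min(aE, bE) + 1L
  gapHi <- max(aS, bS) - 1L
  if (gapLo > gapHi) return(FALSE)
  any(insS >= gapLo & insE <= gapHi)
}

# configuration of a disjoint stranded pair by explicit side enumeration
oracleConfig <- function(aS, aE, aStr, bS, bE, bStr) {
  bRight <- bS > aE
  if (aStr == bStr) {
    if (aStr == "+") { if (bRight) "same_downstream" else "same_upstream" }
    else             { if (bRight) "same_upstream" else "same_downstream" }
  } else {
    if (aStr == "+") { if (bRight) "opposite_tail_to_tail"
                       else "opposite_head_to_head" }
    else             { if (bRight) "opposite_head_to_head"
                       else "opposite_tail_to_tail" }
  }
}

# bases strictly between two disjoint intervals
oracleGap <- function(aS, aE, bS, bE) {
  if (bS > aE) bS - aE - 1L else if (aS > bE) aS - bE - 1L else 0L
}

# strand-aware double-loop tag counting
oracleCountTags <- function(tagPos, tagStr, tagCnt, intS, intE, intStr) {
  total <- 0L
  for (i in seq_along(tagPos)) {
    for (j in seq_along(intS)) {
      if (tagPos[i] >= intS[j] && tagPos[i] <= intE[j] &&
          (intStr[j] == "*" || tagStr[i] == intStr[j])) {
        total <- total + tagCnt[i]
        break
      }
    }
  }
  total
}

# naive O(m^2) Benjamini-Hochberg
oracleBH <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "min")
  vapply(seq_len(m), function(i) {
    cand <- p * m / r
    min(1, min(cand[p >= p[i]]))
  }, 0)
}

# exact upper-tail hypergeometric from binomial coefficients
oracleHyperUpper <- function(N, K, n, k) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# exhaustive-permutation one-sided Mann-Whitney p (a greater)
oracleMWW <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  idx <- utils::combn(length(pooled), n)
  obs <- sum(rank(pooled)[seq_len(n)])
  stats <- apply(idx, 2L, function(ix) sum(rank(pooled)[ix]))
  mean(stats >= obs)
}

# two-stage median: per a-feature median, then across features
oracleTwoStageMedian <- function(aId, rho) {
  stats::median(vapply(unique(aId), function(a)
    stats::median(rho[aId == a]), 0))
}

rg <- function(chr, s, e, strand = "*", ...) {
  GRanges(chr, IRanges(s, e), strand = strand, ...)
}
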