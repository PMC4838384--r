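#' miRNA-target correlation profile against random-target controls
#'
#' For each miRNA, the Spearman correlation of its surrogate-window
#' expression with each of its experimentally validated targets is
#' computed across samples, along with a control built from an equal-size
#' random draw (without replacement) of expressed genes. Only miRNAs and
#' targets with non-zero expression in at least one sample enter. The
#' per-miRNA median distributions (real vs random) are compared with a
#' one-sided KS test for the real targets lying lower.
#'
#' @param expr \code{\link{VlincExperiment}} or matrix whose rows include
#'   the miRNA surrogate features and the genes.
#' @param targets named list: miRNA feature id -> character vector of
#'   validated target gene ids.
#' @param geneIds character vector naming the gene universe rows.
#' @param seed integer seed for the random-target draws.
#' @return list: \code{summary} (data.frame mirna, median_rho_real,
#'   median_rho_random, n_targets_used), \code{ks_p}, \code{n_dropped}.
#' @export
mirnaTargetProfile <- function(expr, targets, geneIds, seed = 1L) {
  m <- if (is(expr, "VlincExperiment")) rpkmValues(expr) else expr
  expressed <- rownames(m)[rowSums(m != 0) > 0]
  pool <- intersect(geneIds, expressed)
  set.seed(seed)
  rows <- list(); dropped <- 0L
  for (mir in names(targets)) {
    if (!(mir %in% expressed)) { dropped <- dropped + 1L; next }
    tg <- intersect(targets[[mir]], pool)
    if (!length(tg)) { dropped <- dropped + 1L; next }
    rnd <- sample(setdiff(pool, targets[[mir]]), length(tg))
    rhoReal <- pairRho(m, rep(mir, length(tg)), tg)
    rhoRand <- pairRho(m, rep(mir, length(rnd)), rnd)
    rows[[length(rows) + 1L]] <- data.frame(
      mirna = mir,
      median_rho_real = stats::median(rhoReal, na.rm = TRUE),
      median_rho_random = stats::median(rhoRand, na.rm = TRUE),
      n_targets_used = length(tg), stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  ks <- if (!is.null(summary) && nrow(summary) >= 2L)
    ksOneSided(summary$median_rho_real, summary$median_rho_random,
               "a_less")$p
  else NA_real_
  list(summary = summary, ks_p = ks, n_dropped = dropped)
}

#' Correlation of feature groups with pluripotency factors over a time course
#'
#' Spearman correlation of every feature with each factor's expression
#' across the time points, summarized for the five promoter/binding
#' categories (no_promoter, LTR or nonLTR without the factor's binding,
#' LTR or nonLTR with it). All pairwise one-sided KS contrasts between
#' groups are reported per factor.
#'
#' @param expr expression over the time-course columns only (matrix or
#'   \code{\link{VlincExperiment}}).
#' @param tfIds named character vector: factor name -> its transcript's
#'   feature id.
#' @param annotation \code{\link{annotateVlincs}}-style table with
#'   \code{vlinc_id}, \code{category} and one logical column per factor.
#' @return list per factor: \code{rho} (data.frame feature, group, rho)
#'   and \code{contrasts} (data.frame group_a, group_b, p for a greater).
#' @export
tfGroupCorrelations <- function(expr, tfIds, annotation) {
  m <- if (is(expr, "VlincExperiment")) rpkmValues(expr) else expr
  if (ncol(m) < 4L) stop("time course must have at least 4 points")
  ann <- annotation[annotation$vlinc_id %in% rownames(m), ]
  out <- list()
  for (f in names(tfIds)) {
    y <- m[tfIds[[f]], ]
    bound <- ann[[f]]
    group <- ifelse(ann$category == "no_promoter", "no_promoter",
                    paste0(ann$category,
                           ifelse(bound, "_ChIPseq+", "_ChIPseq-")))
    rho <- spearmanRows(m[ann$vlinc_id, , drop = FALSE], y)
    df <- data.frame(feature = ann$vlinc_id, group = group, rho = rho,
                     stringsAsFactors = FALSE)
    groups <- unique(group)
    cons <- list()
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i == j) next
      a <- df$rho[df$group == groups[i] & !is.na(df$rho)]
      b <- df$rho[df$group == groups[j] & !is.na(df$rho)]
      if (!length(a) || !length(b)) next
      cons[[length(cons) + 1L]] <- data.frame(
        group_a = groups[i], group_b = groups[j],
        p = ksOneSided(a, b, "a_greater")$p, stringsAsFactors = FALSE)
    }
    out[[f]] <- list(rho = df, contrasts = do.call(rbind, cons))
  }
  out
}

#' Sample non-overlapping random genomic regions
#'
#' @param n number of regions.
#' @param regionLength region width in bp.
#' @param chromLengths named vector of chromosome lengths.
#' @return \code{GRanges} of \code{n} disjoint regions.
#' @export
randomRegions <- function(n, regionLength, chromLengths) {
  if (sum(pmax(0, chromLengths - regionLength)) < n * regionLength * 2)
    stop("genome too small for non-overlapping sampling")
  keptChr <- character(0); keptStart <- numeric(0)
  rounds <- 0L
  while (length(keptStart) < n) {
    rounds <- rounds + 1L
    if (rounds > 50L) stop("genome too small for non-overlapping sampling")
    m <- 2L * (n - length(keptStart)) + 8L
    chrom <- sample(names(chromLengths), m, replace = TRUE,
                    prob = chromLengths / sum(chromLengths))
    start <- floor(stats::runif(m, 1, chromLengths[chrom] - regionLength))
    chrom <- c(keptChr, chrom); start <- c(keptStart, start)
    ord <- order(chrom, start)
    chrom <- chrom[ord]; start <- start[ord]
    # greedy left-to-right selection of non-overlapping candidates
    keep <- logical(length(start)); lastEnd <- -Inf; lastChr <- ""
    for (i in seq_along(start)) {
      if (chrom[i] != lastChr || start[i] > lastEnd) {
        keep[i] <- TRUE
        lastChr <- chrom[i]; lastEnd <- start[i] + regionLength - 1
      }
    }
    keptChr <- chrom[keep]; keptStart <- start[keep]
    if (length(keptStart) > n) {
      take <- sort(sample.int(length(keptStart), n))
      keptChr <- keptChr[take]; keptStart <- keptStart[take]
    }
  }
  GRanges(keptChr, IRanges(keptStart, width = regionLength))
}

#' Enrichment of ChIP-seq signal in vlincRNA 5' flanks
#'
#' Observed statistic: total peak-tag count overlapping the +/- flank
#' windows around the annotated vlincRNA 5' ends. Null: the count in
#' freshly sampled non-overlapping random regions of matching number and
#' length, repeated \code{nPerm} times; the empirical p-value uses the
#' add-one estimator, so signal exceeding every draw at 1000 permutations
#' reports 1/1001 (< 0.001).
#'
#' @param vlincs stranded \code{GRanges}.
#' @param peaks \code{GRanges} of ChIP-seq peaks (or read positions).
#' @param chromLengths named chromosome-length vector.
#' @param flank half-width of the 5'-flank windows (default 5000).
#' @param regionLength random-region width (default 2 * flank).
#' @param nPerm permutations (default 1000).
#' @param seed integer seed.
#' @return list: \code{observed}, \code{p}, \code{nullDraws}.
#' @export
flankPeakEnrichment <- function(vlincs, peaks, chromLengths, flank = 5000L,
                                regionLength = 2L * flank, nPerm = 1000L,
                                seed = 1L) {
  flanks <- flankWindow(vlincs, flank)
  observed <- sum(GenomicRanges::countOverlaps(peaks, flanks,
                                               ignore.strand = TRUE) > 0)
  if (!length(peaks))
    return(list(observed = 0L, p = 1, nullDraws = rep(0L, nPerm)))
  set.seed(seed)
  nullDraws <- vapply(seq_len(nPerm), function(i) {
    rr <- randomRegions(length(vlincs), regionLength, chromLengths)
    sum(GenomicRanges::countOverlaps(peaks, rr, ignore.strand = TRUE) > 0)
  }, 0)
  list(observed = observed, p = empiricalPermP(observed, nullDraws),
       nullDraws = nullDraws)
}

#' Per-promoter ChIP-seq signal by category
#'
#' Counts peak tags per promoter for each factor, keeping only promoters
#' with at least one tag, and returns the per-category count
#' distributions.
#'
#' @param promoterSets named list of \code{GRanges} promoter sets (e.g.
#'   LTR_vlinc, nonLTR_vlinc, LTR_gene, nonLTR_gene).
#' @param peakTags named \code{GRangesList}: factor -> tag/peak positions.
#' @return data.frame: set, factor, promoter index, count (zero-count
#'   promoters excluded).
#' @export
promoterPeakSignal <- function(promoterSets, peakTags) {
  rows <- list()
  for (nm in names(promoterSets)) {
    pr <- promoterSets[[nm]]
    if (!length(pr)) next
    for (f in names(peakTags)) {
      cnt <- GenomicRanges::countOverlaps(pr, peakTags[[f]],
                                          ignore.strand = TRUE)
      keep <- cnt > 0
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        set = nm, factor = f, promoter = which(keep),
        count = cnt[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(set = character(0), factor = character(0),
                      promoter = integer(0), count = integer(0)))
  do.call(rbind, rows)
}
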