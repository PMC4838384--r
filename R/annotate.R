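#' Assign promoter elements to features by TSS proximity
#'
#' A promoter of any chromatin state (Active/Weak/Poised) whose interval
#' overlaps the window [TSS - w, TSS + w] is assigned to the feature.
#' VlincRNAs conventionally use w = 5000 (their 5' ends are imprecise);
#' known genes use w = 1000. Unresolved-strand features have no defined
#' TSS and receive no promoter.
#'
#' @param features \code{GRanges} with an id in the first mcols column.
#' @param promoters unstranded \code{GRanges} promoter track.
#' @param window half-width w in bp.
#' @return list, one integer vector of promoter indices per feature.
#' @export
assignPromoters <- function(features, promoters, window = 5000L) {
  res <- vector("list", length(features))
  str <- as.character(GenomicRanges::strand(features))
  resolved <- str != "*"
  if (any(!resolved))
    message(sum(!resolved), " feature(s) with unresolved strand get no promoter")
  if (!length(promoters) || !any(resolved)) {
    res[] <- list(integer(0))
    return(res)
  }
  tss <- fivePrimePos(features)
  win <- GRanges(seqnames(features),
                 IRanges(pmax(1L, tss - window), tss + window))
  hit <- GenomicRanges::findOverlaps(win[resolved], promoters,
                                     ignore.strand = TRUE)
  byFeat <- split(S4Vectors::subjectHits(hit), S4Vectors::queryHits(hit))
  res[] <- list(integer(0))
  idx <- which(resolved)
  for (k in names(byFeat)) res[[idx[as.integer(k)]]] <- unname(byFeat[[k]])
  res
}

#' Promoter category (LTR / nonLTR / no_promoter)
#'
#' @param assigned list of promoter index vectors (from
#'   \code{\link{assignPromoters}}).
#' @param promoters the promoter \code{GRanges} the indices refer to.
#' @param ltr \code{GRanges} of LTR repeats; overlap of any assigned
#'   promoter with any LTR repeat (any strand) makes the category "LTR".
#' @return character vector of categories.
#' @export
promoterCategory <- function(assigned, promoters, ltr) {
  ltrProm <- if (length(ltr) && length(promoters))
    GenomicRanges::countOverlaps(promoters, ltr, ignore.strand = TRUE) > 0
  else rep(FALSE, length(promoters))
  vapply(assigned, function(idx) {
    if (!length(idx)) "no_promoter"
    else if (any(ltrProm[idx])) "LTR"
    else "nonLTR"
  }, "")
}

#' Per-factor TF-binding status of assigned promoters
#'
#' A factor flag is true when any assigned promoter overlaps any ChIP-seq
#' peak of that factor.
#'
#' @param assigned list of promoter index vectors.
#' @param promoters the promoter \code{GRanges}.
#' @param tfPeaks named \code{GRangesList} of peaks per factor.
#' @return logical matrix, features x factors.
#' @export
tfBindingStatus <- function(assigned, promoters, tfPeaks) {
  out <- matrix(FALSE, length(assigned), length(tfPeaks),
                dimnames = list(NULL, names(tfPeaks)))
  for (f in names(tfPeaks)) {
    bound <- if (length(promoters) && length(tfPeaks[[f]]))
      GenomicRanges::countOverlaps(promoters, tfPeaks[[f]],
                                   ignore.strand = TRUE) > 0
    else rep(FALSE, length(promoters))
    out[, f] <- vapply(assigned, function(idx) any(bound[idx]), TRUE)
  }
  out
}

#' Distal status: no annotated gene within the threshold
#'
#' A feature is distal when the body-to-body gap to the nearest gene on
#' either side and either strand is at least the threshold ("at least
#' 50 kb": a gap of exactly the threshold still counts as distal).
#'
#' @param features \code{GRanges}.
#' @param genes \code{GRanges} of gene bodies.
#' @param threshold minimum separation in bp (default 50000).
#' @return logical vector.
#' @export
distalFlag <- function(features, genes, threshold = 50000L) {
  if (!length(genes)) return(rep(TRUE, length(features)))
  d <- GenomicRanges::distanceToNearest(features, genes,
                                        ignore.strand = TRUE)
  out <- rep(TRUE, length(features))
  out[S4Vectors::queryHits(d)] <- mcols(d)$distance >= threshold
  out
}

#' Annotate vlincRNAs: promoter category, TF binding, distal status
#'
#' @param bundle an \code{\link{AnnotationBundle}}.
#' @param window promoter-assignment half-width for vlincRNAs (bp).
#' @param distalThreshold distal separation threshold (bp).
#' @return \code{DataFrame} with one row per vlincRNA: \code{vlinc_id},
#'   \code{category}, \code{promoters} (IntegerList), per-factor logical
#'   columns, \code{all_three_tfs} and \code{distal}.
#' @export
annotateVlincs <- function(bundle, window = 5000L, distalThreshold = 50000L) {
  vl <- vlincRanges(bundle)
  pr <- promoterElements(bundle)
  assigned <- assignPromoters(vl, pr, window)
  cat <- promoterCategory(assigned, pr, ltrRepeats(bundle))
  tf <- tfBindingStatus(assigned, pr, tfPeaks(bundle))
  out <- DataFrame(vlinc_id = mcols(vl)$vlinc_id,
                   category = cat,
                   promoters = methods::as(assigned, "IntegerList"))
  for (f in colnames(tf)) out[[f]] <- tf[, f]
  out$all_three_tfs <- if (ncol(tf)) apply(tf, 1L, all) else
    rep(FALSE, length(vl))
  out$any_tf <- if (ncol(tf)) apply(tf, 1L, any) else rep(FALSE, length(vl))
  out$distal <- distalFlag(vl, geneBodies(bundle), distalThreshold)
  out
}
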