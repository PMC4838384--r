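#' Designate standalone vlincRNAs
#'
#' A vlincRNA is standalone when, on each of its two sides (5' and 3'),
#' either no same-strand gene lies within the distance threshold
#' (body-end to body-end, inclusive at exactly the threshold) or every
#' same-strand gene within the threshold is separated from the vlincRNA by
#' an insulator element lying wholly in the gap between them. A
#' same-strand gene overlapping the vlincRNA always blocks (the gap is
#' empty, so no insulator can separate). Only same-strand genes are
#' considered; opposite-strand neighbors never block.
#'
#' The reason field classifies the clearance: \code{far_both_sides} (no
#' same-strand gene within the threshold on either side),
#' \code{insulator_both_sides} (genes present on both sides, all separated),
#' \code{far_one_insulator_other}, or \code{not_standalone}.
#'
#' @param vlincs stranded \code{GRanges} with \code{vlinc_id}.
#' @param genes \code{GRanges} of gene bodies.
#' @param insulators \code{GRanges} insulator track.
#' @param threshold distance threshold in bp (default 50000).
#' @param inclusive whether a gene at exactly the threshold counts as
#'   "within" (default TRUE).
#' @return data.frame: \code{vlinc_id}, \code{standalone}, \code{reason}.
#' @export
designateStandalone <- function(vlincs, genes, insulators,
                                threshold = 50000L, inclusive = TRUE) {
  n <- length(vlincs)
  standalone <- logical(n)
  reason <- character(n)
  vstr <- as.character(GenomicRanges::strand(vlincs))
  gstr <- as.character(GenomicRanges::strand(genes))
  gs <- GenomicRanges::start(genes); ge <- GenomicRanges::end(genes)
  gchr <- as.character(seqnames(genes))
  for (i in seq_len(n)) {
    v <- vlincs[i]
    sameStrand <- which(gchr == as.character(seqnames(v)) &
                          gstr == vstr[i])
    vs <- GenomicRanges::start(v); ve <- GenomicRanges::end(v)
    gap <- pmax(0L, pmax(gs[sameStrand] - ve, vs - ge[sameStrand]) - 1L)
    overl <- gs[sameStrand] <= ve & ge[sameStrand] >= vs
    within <- if (inclusive) gap <= threshold else gap < threshold
    near <- sameStrand[within | overl]
    if (!length(near)) {
      standalone[i] <- TRUE; reason[i] <- "far_both_sides"
      next
    }
    # split near genes into the vlincRNA's 5' and 3' sides
    leftOf <- ge[near] < vs          # genomically left (overlaps: both)
    rightOf <- gs[near] > ve
    onLeft <- near[leftOf | (!leftOf & !rightOf)]
    onRight <- near[rightOf | (!leftOf & !rightOf)]
    if (vstr[i] == "-") { tmp <- onLeft; onLeft <- onRight; onRight <- tmp }
    side5 <- onLeft; side3 <- onRight   # now in transcript orientation
    clear <- function(side) {
      if (!length(side)) return("far")
      sep <- separatedByInsulator(rep(v, length(side)), genes[side],
                                  insulators)
      if (all(sep)) "insulator" else "blocked"
    }
    c5 <- clear(side5); c3 <- clear(side3)
    if (c5 == "blocked" || c3 == "blocked") {
      reason[i] <- "not_standalone"
    } else {
      standalone[i] <- TRUE
      reason[i] <- if (c5 == "far" && c3 == "far") "far_both_sides"
        else if (c5 == "insulator" && c3 == "insulator")
          "insulator_both_sides"
        else "far_one_insulator_other"
    }
  }
  data.frame(vlinc_id = mcols(vlincs)$vlinc_id,
             standalone = standalone, reason = reason,
             stringsAsFactors = FALSE)
}

#' Merge standalone vlincRNAs into vlincRNA genes
#'
#' Strand-specific merge of the standalone vlincRNA intervals; overlapping
#' or book-ended same-strand vlincRNAs collapse into one gene whose
#' interval spans their union and which records its member ids.
#'
#' @param vlincs stranded \code{GRanges} of standalone vlincRNAs with
#'   \code{vlinc_id}.
#' @return \code{GRanges} with mcols \code{gene_id}, \code{member_ids},
#'   \code{n_members}.
#' @export
buildGenes <- function(vlincs) {
  if (!length(vlincs)) {
    out <- GRanges()
    mcols(out)$gene_id <- character(0)
    return(out)
  }
  g <- strandMerge(vlincs)
  mcols(g)$gene_id <- paste0("vg", seq_along(g))
  g
}
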