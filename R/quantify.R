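#' Count 5'-tags falling in feature intervals
#'
#' A tag is counted for an interval when its 5' end lies inside the
#' interval (boundary bases included), and -- unless the feature is
#' unstranded -- only when it maps to the feature's strand. This is the
#' strand-specific "internal" counting rule; flank-mode counting simply
#' passes the window around the annotated 5' end as the interval set.
#'
#' @param tagset a \code{\link{TagSet}}.
#' @param featureIntervals \code{GRanges}: the masked fragments of one
#'   feature (internal mode) or its 5'-flank window (flank mode).
#' @return integer sum of multiplicities of qualifying tags.
#' @export
countTags <- function(tagset, featureIntervals) {
  stopifnot(is(tagset, "TagSet"), is(featureIntervals, "GRanges"))
  tags <- tagPositions(tagset)
  if (!length(tags) || !length(featureIntervals)) return(0L)
  fstr <- as.character(GenomicRanges::strand(featureIntervals))
  ignore <- all(fstr == "*")
  hit <- GenomicRanges::findOverlaps(tags, featureIntervals,
                                     ignore.strand = ignore)
  as.integer(sum(mcols(tags)$count[unique(S4Vectors::queryHits(hit))]))
}

#' Flank window around a feature's annotated 5' end
#'
#' @param features stranded \code{GRanges}.
#' @param w half-width in bp.
#' @return \code{GRanges} windows [TSS - w, TSS + w] on the feature strand.
#' @export
flankWindow <- function(features, w) {
  tss <- fivePrimePos(features)
  GRanges(seqnames(features), IRanges(pmax(1L, tss - w), tss + w),
          strand = GenomicRanges::strand(features))
}

#' Effective (masked) length of a vlincRNA
#'
#' Length of the vlincRNA body after removing gene exons and rRNA repeats
#' (always, irrespective of strand) and optionally EST-5' windows
#' (same-strand) or promoter windows (any strand), each extended by 1 kb on
#' both sides. Genes instead use the sum of their exon lengths.
#'
#' @param vlinc single-range stranded \code{GRanges}.
#' @param bundle an \code{\link{AnnotationBundle}}.
#' @param extraMasks \code{"none"}, \code{"est_5p"} or \code{"promoters"}.
#' @param pad extension of the extra-mask intervals (bp, default 1000).
#' @return list with \code{fragments} (\code{GRanges}) and \code{length};
#'   zero length means the feature is fully masked and should be dropped.
#' @export
effectiveVlincSpace <- function(vlinc, bundle,
                                extraMasks = c("none", "est_5p", "promoters"),
                                pad = 1000L) {
  extraMasks <- match.arg(extraMasks)
  base <- c(granges(unlist(geneExons(bundle))),
            granges(rrnaRepeats(bundle)))
  fr <- subtractMasks(vlinc, base, "any")
  if (extraMasks == "est_5p" && length(est5pEnds(bundle))) {
    est <- est5pEnds(bundle)
    win <- GRanges(seqnames(est),
                   IRanges(pmax(1L, GenomicRanges::start(est) - pad),
                           GenomicRanges::end(est) + pad),
                   strand = GenomicRanges::strand(est))
    fr <- subtractMasks(fr, win, "same")
  } else if (extraMasks == "promoters" && length(promoterElements(bundle))) {
    pr <- promoterElements(bundle)
    win <- GRanges(seqnames(pr),
                   IRanges(pmax(1L, GenomicRanges::start(pr) - pad),
                           GenomicRanges::end(pr) + pad))
    fr <- subtractMasks(fr, win, "any")
  }
  list(fragments = fr, length = sum(GenomicRanges::width(fr)))
}

#' RPKM-style normalization
#'
#' raw / (informative * length) * 1e9 for genes (and miRNA surrogate
#' windows), raw / (informative * length) * 1e11 for vlincRNAs -- i.e.
#' per kilobase of masked feature length and per 1 M (genes) or 100 M
#' (vlincRNAs) informative reads.
#'
#' @param raw raw tag count (vectorized).
#' @param informative informative-read total (> 0).
#' @param length effective feature length in bases (> 0).
#' @param kind \code{"gene"}, \code{"vlinc"} or \code{"mirna"}.
#' @return normalized expression value.
#' @examples
#' rpkm(100, 1e7, 1000, "gene")  # 10
#' @export
rpkm <- function(raw, informative, length, kind = "gene") {
  if (any(informative <= 0)) stop("informative reads must be > 0")
  if (any(length <= 0)) stop("feature length must be > 0")
  scale <- ifelse(kind == "vlinc", 1e11, 1e9)
  raw / (informative * length) * scale
}

#' RNA-seq style fractional counting
#'
#' A read wholly inside the feature's interval set counts 1; a read
#' crossing an interval border counts 0.5. The strand rule matches
#' \code{\link{countTags}}.
#'
#' @param reads \code{GRanges} of aligned read intervals.
#' @param featureIntervals \code{GRanges} intervals of one feature.
#' @return fractional count.
#' @export
rnaseqCount <- function(reads, featureIntervals) {
  if (!length(reads) || !length(featureIntervals)) return(0)
  fstr <- as.character(GenomicRanges::strand(featureIntervals))
  ignore <- all(fstr == "*")
  inside <- GenomicRanges::countOverlaps(reads, featureIntervals,
                                         type = "within",
                                         ignore.strand = ignore) > 0
  touching <- GenomicRanges::countOverlaps(reads, featureIntervals,
                                           ignore.strand = ignore) > 0
  sum(inside) + 0.5 * sum(touching & !inside)
}

#' Call the strand of an unassigned feature from read counts
#'
#' Compares tag counts aligned to either strand within the feature body;
#' the strand with more tags wins, a tie (including 0 vs 0) stays
#' unresolved (\code{"*"}).
#'
#' @param feature single-range \code{GRanges} (strand ignored).
#' @param tagset a \code{\link{TagSet}}.
#' @return \code{"+"}, \code{"-"} or \code{"*"}.
#' @export
callStrand <- function(feature, tagset) {
  body <- granges(feature)
  GenomicRanges::strand(body) <- "+"
  plus <- countTags(tagset, body)
  GenomicRanges::strand(body) <- "-"
  minus <- countTags(tagset, body)
  if (plus > minus) "+" else if (minus > plus) "-" else "*"
}

#' Aggregate 5'-tag density profile around annotated vlincRNA 5' ends
#'
#' Each vlincRNA contributes a 10 kb window centered on its annotated 5'
#' end (the left boundary for plus-strand, the right boundary for
#' minus-strand features), split into 20 bins of 500 bp reported in
#' transcript orientation (bins 1-10 upstream, 11-20 downstream; a tag at
#' the annotated 5' base falls in bin 11). Same-strand tags whose 5' end
#' lies inside a bin are counted and summed across all vlincRNAs and
#' samples. Named outlier features can be excluded, mirroring the removal
#' of a few extreme features in practice.
#'
#' @param vlincs stranded \code{GRanges} with \code{vlinc_id}.
#' @param tagsets list of \code{\link{TagSet}}.
#' @param window half-width (default 5000).
#' @param bin bin width (default 500).
#' @param exclude character vector of vlinc_ids to drop as outliers.
#' @return numeric vector of \code{2 * window / bin} summed counts.
#' @export
tssDensityProfile <- function(vlincs, tagsets, window = 5000L, bin = 500L,
                              exclude = character(0)) {
  nb <- as.integer(2L * window / bin)
  prof <- numeric(nb)
  keep <- !(mcols(vlincs)$vlinc_id %in% exclude)
  vl <- vlincs[keep]
  if (!length(vl)) return(prof)
  tss <- fivePrimePos(vl)
  minus <- as.character(GenomicRanges::strand(vl)) == "-"
  # transcript-oriented window: offset `window` (bin 11 at default sizes)
  # lands exactly on the annotated 5' base for either strand
  win <- GRanges(seqnames(vl),
                 IRanges(pmax(1L, tss - window + minus),
                         tss + window - 1L + minus),
                 strand = GenomicRanges::strand(vl))
  for (ts in tagsets) {
    tags <- tagPositions(ts)
    if (!length(tags)) next
    hit <- GenomicRanges::findOverlaps(tags, win, ignore.strand = FALSE)
    if (!length(hit)) next
    q <- S4Vectors::queryHits(hit); s <- S4Vectors::subjectHits(hit)
    pos <- GenomicRanges::start(tags)[q]
    off <- ifelse(minus[s], tss[s] + window - pos, pos - (tss[s] - window))
    b <- pmin(nb, pmax(1L, off %/% bin + 1L))
    cnt <- mcols(tags)$count[q]
    prof <- prof + vapply(seq_len(nb), function(i) sum(cnt[b == i]), 0)
  }
  prof
}

#' Merge sequencing channels of one biological sample
#'
#' Sums tag multiplicities position-wise and adds the informative totals.
#'
#' @param tagsets list of \code{\link{TagSet}} channels of one sample.
#' @param sampleId identifier for the merged set (default: first channel's).
#' @return a single \code{\link{TagSet}}.
#' @export
mergeChannels <- function(tagsets, sampleId = NULL) {
  stopifnot(length(tagsets) >= 1L)
  if (is.null(sampleId)) sampleId <- sampleId(tagsets[[1L]])
  tags <- unlist(GRangesList(lapply(tagsets, tagPositions)))
  TagSet(sampleId, tags,
         sum(vapply(tagsets, informativeReads, 0)))
}

#' Quantify expression of genes, vlincRNAs and miRNA windows
#'
#' The complete internal-counting workflow: builds each feature's counting
#' space (gene exons; vlincRNA bodies masked for exons and rRNA repeats,
#' optionally also EST-5' or promoter windows; miRNA surrogate windows),
#' counts same-strand tags per feature and sample, and normalizes with the
#' RPKM formulas. Features whose counting space is fully masked are
#' dropped with a message.
#'
#' @param bundle an \code{\link{AnnotationBundle}}.
#' @param tagsets named list of \code{\link{TagSet}} (one per sample).
#' @param mode \code{"internal"} (masked bodies / exons) or \code{"flank"}
#'   (window around the annotated 5' end).
#' @param flankWidth half-width for flank mode (default 5000).
#' @param extraMasks vlincRNA extra-mask option, see
#'   \code{\link{effectiveVlincSpace}}.
#' @param mirnas optional \code{GRanges} of pre-miRNA loci with
#'   \code{mirna_id}; quantified over sense-strand +/-1 kb windows.
#' @param colData optional per-sample metadata \code{DataFrame}/data.frame
#'   whose rows match \code{names(tagsets)}.
#' @return a \code{\link{VlincExperiment}}.
#' @export
quantifyExpression <- function(bundle, tagsets,
                               mode = c("internal", "flank"),
                               flankWidth = 5000L,
                               extraMasks = "none",
                               mirnas = NULL, colData = NULL) {
  mode <- match.arg(mode)
  genes <- geneBodies(bundle)
  vlincs <- vlincRanges(bundle)

  spaces <- list(); kinds <- character(0)
  if (length(genes)) {
    gids <- mcols(genes)$tx_id
    if (mode == "internal") {
      exAll <- granges(unlist(geneExons(bundle)))
      GenomicRanges::strand(exAll) <-
        rep(as.character(GenomicRanges::strand(genes)),
            lengths(geneExons(bundle)))
      byGene <- GenomicRanges::split(
        exAll, factor(rep(seq_along(genes), lengths(geneExons(bundle))),
                      levels = seq_along(genes)))
      spaces <- as.list(byGene)
    } else {
      fw <- flankWindow(genes, 1000L)
      spaces <- lapply(seq_along(genes), function(i) fw[i])
    }
    names(spaces) <- gids
    kinds <- c(kinds, stats::setNames(rep("gene", length(genes)), gids))
  }
  if (length(vlincs)) {
    vids <- mcols(vlincs)$vlinc_id
    baseMasks <- c(granges(unlist(geneExons(bundle))),
                   granges(rrnaRepeats(bundle)))
    extraWin <- NULL; extraRule <- "any"
    if (extraMasks == "est_5p" && length(est5pEnds(bundle))) {
      est <- est5pEnds(bundle)
      extraWin <- GRanges(seqnames(est),
                          IRanges(pmax(1L, GenomicRanges::start(est) - 1000L),
                                  GenomicRanges::end(est) + 1000L),
                          strand = GenomicRanges::strand(est))
      extraRule <- "same"
    } else if (extraMasks == "promoters" &&
               length(promoterElements(bundle))) {
      pr <- promoterElements(bundle)
      extraWin <- GRanges(seqnames(pr),
                          IRanges(pmax(1L, GenomicRanges::start(pr) - 1000L),
                                  GenomicRanges::end(pr) + 1000L))
    }
    for (i in seq_along(vlincs)) {
      spaces[[vids[i]]] <- if (mode == "internal") {
        fr <- subtractMasks(vlincs[i], baseMasks, "any")
        if (!is.null(extraWin)) fr <- subtractMasks(fr, extraWin, extraRule)
        fr
      } else flankWindow(vlincs[i], flankWidth)
    }
    kinds <- c(kinds, stats::setNames(rep("vlinc", length(vlincs)), vids))
  }
  if (!is.null(mirnas) && length(mirnas)) {
    mids <- mcols(mirnas)$mirna_id
    win <- GRanges(seqnames(mirnas),
                   IRanges(pmax(1L, GenomicRanges::start(mirnas) - 1000L),
                           GenomicRanges::end(mirnas) + 1000L),
                   strand = GenomicRanges::strand(mirnas))
    for (i in seq_along(mirnas)) spaces[[mids[i]]] <- win[i]
    kinds <- c(kinds, stats::setNames(rep("mirna", length(mirnas)), mids))
  }

  lens <- vapply(spaces, function(s) sum(GenomicRanges::width(s)), 0)
  drop <- names(lens)[lens == 0]
  if (length(drop)) {
    message("dropping ", length(drop),
            " fully masked feature(s): ", paste(drop, collapse = ", "))
    spaces <- spaces[lens > 0]; kinds <- kinds[lens > 0]
    lens <- lens[lens > 0]
  }
  ids <- names(spaces)

  # one flattened interval set for a single findOverlaps per sample
  flat <- unlist(GRangesList(spaces))
  featIdx <- rep(seq_along(spaces), lengths(spaces))

  counts <- matrix(0, length(ids), length(tagsets),
                   dimnames = list(ids, names(tagsets)))
  informative <- numeric(length(tagsets))
  for (s in seq_along(tagsets)) {
    ts <- tagsets[[s]]
    informative[s] <- informativeReads(ts)
    tags <- tagPositions(ts)
    if (!length(tags)) next
    hit <- GenomicRanges::findOverlaps(tags, flat, ignore.strand = FALSE)
    if (!length(hit)) next
    pairKey <- paste0(S4Vectors::queryHits(hit), "_",
                      featIdx[S4Vectors::subjectHits(hit)])
    dedup <- !duplicated(pairKey)   # a tag counts once per feature
    q <- S4Vectors::queryHits(hit)[dedup]
    f <- featIdx[S4Vectors::subjectHits(hit)][dedup]
    agg <- rowsum(as.numeric(mcols(tags)$count[q]), f)
    counts[as.integer(rownames(agg)), s] <- agg[, 1L]
  }
  if (any(informative <= 0)) stop("a sample has no informative reads")

  vals <- counts / (matrix(informative, length(ids), length(tagsets),
                           byrow = TRUE) * lens) *
    ifelse(kinds == "vlinc", 1e11, 1e9)
  cd <- NULL
  if (!is.null(colData)) cd <- S4Vectors::DataFrame(colData)
  VlincExperiment(vals, kind = unname(kinds), effectiveLength = unname(lens),
                  colData = cd)
}
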