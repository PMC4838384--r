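#' Subtract mask intervals from a target interval
#'
#' Removes every base of \code{target} covered by a qualifying mask and
#' returns the remaining fragments. Used to build the "effective" vlincRNA
#' territory: gene exons and rRNA repeats are always removed irrespective
#' of strand, and optional EST-5'/promoter windows can be removed under a
#' same-strand rule.
#'
#' @param target a single-range \code{GRanges} (or a \code{GRanges} whose
#'   ranges are treated independently).
#' @param masks \code{GRanges} of mask intervals; only masks on the target's
#'   chromosome act.
#' @param strandRule \code{"any"} (default): masks act regardless of strand;
#'   \code{"same"}: only masks on the same strand as the target act
#'   (unstranded masks act on both).
#' @return \code{GRanges} of disjoint, sorted fragments contained in
#'   \code{target}. Full masking legally yields an empty result. The summed
#'   width of the result is the residual (effective) length.
#' @examples
#' tgt <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100), strand = "+")
#' msk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(41, 60))
#' frag <- subtractMasks(tgt, msk)
#' sum(GenomicRanges::width(frag))  # 80
#' @export
subtractMasks <- function(target, masks, strandRule = c("any", "same")) {
  strandRule <- match.arg(strandRule)
  stopifnot(is(target, "GRanges"), is(masks, "GRanges"))
  if (!length(masks)) return(GenomicRanges::sort(granges(target),
                                                 ignore.strand = TRUE))
  if (strandRule == "same") {
    tstr <- as.character(GenomicRanges::strand(target))
    mstr <- as.character(GenomicRanges::strand(masks))
    keepStr <- unique(c(tstr, "*"))
    masks <- masks[mstr %in% keepStr]
  }
  out <- GenomicRanges::setdiff(granges(target), granges(masks),
                                ignore.strand = TRUE)
  # setdiff drops strand context; restore the target's strand per fragment
  hit <- GenomicRanges::findOverlaps(out, target, ignore.strand = TRUE)
  GenomicRanges::strand(out)[S4Vectors::queryHits(hit)] <-
    as.character(GenomicRanges::strand(target))[S4Vectors::subjectHits(hit)]
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Residual length after masking
#'
#' @param target,masks,strandRule as in \code{\link{subtractMasks}}.
#' @return total unmasked bases of \code{target}.
#' @export
residualLength <- function(target, masks, strandRule = c("any", "same")) {
  sum(GenomicRanges::width(subtractMasks(target, masks, strandRule)))
}

#' Is a pair of transcripts separated by an insulator?
#'
#' Two transcripts count as insulator-separated when at least one insulator
#' element lies wholly within the gap between their facing ends. An
#' insulator merely overlapping either transcript does not separate, and
#' overlapping transcripts (empty gap) are never separated. Insulator
#' strand is ignored.
#'
#' @param a,b parallel \code{GRanges} on the same chromosome (recycled if
#'   one has length 1).
#' @param insulators \code{GRanges} of insulator elements.
#' @return logical vector, one flag per pair.
#' @export
separatedByInsulator <- function(a, b, insulators) {
  stopifnot(is(a, "GRanges"), is(b, "GRanges"))
  if (length(a) == 1L && length(b) > 1L) a <- rep(a, length(b))
  if (length(b) == 1L && length(a) > 1L) b <- rep(b, length(a))
  stopifnot(length(a) == length(b))
  if (!length(a)) return(logical(0))
  gap <- GenomicRanges::pgap(granges(a), granges(b), ignore.strand = TRUE)
  ok <- GenomicRanges::width(gap) > 0
  res <- rep(FALSE, length(a))
  if (any(ok) && length(insulators)) {
    hit <- GenomicRanges::findOverlaps(insulators, gap[ok],
                                       type = "within",
                                       ignore.strand = TRUE)
    res[which(ok)[unique(S4Vectors::subjectHits(hit))]] <- TRUE
  }
  res
}

#' Strand-specific merge of intervals
#'
#' Merges overlapping or book-ended intervals separately per strand, the
#' operation that collapses standalone vlincRNAs into vlincRNA genes.
#' Adjacent (zero-gap) intervals merge; intervals on different strands
#' never interact.
#'
#' @param gr \code{GRanges}; an id metadata column (\code{vlinc_id} or the
#'   first mcols column) is propagated into a comma-free CharacterList of
#'   member ids.
#' @return \code{GRanges} of merged intervals, with mcols \code{member_ids}
#'   (a \code{CharacterList}) and \code{n_members}.
#' @export
strandMerge <- function(gr) {
  stopifnot(is(gr, "GRanges"))
  ids <- mcols(gr)$vlinc_id
  if (is.null(ids) && ncol(mcols(gr)) >= 1L && is.atomic(mcols(gr)[[1L]]))
    ids <- as.character(mcols(gr)[[1L]])
  if (is.null(ids)) ids <- as.character(seq_along(gr))
  red <- GenomicRanges::reduce(granges(gr), with.revmap = TRUE,
                               ignore.strand = FALSE)
  revmap <- mcols(red)$revmap
  mcols(red) <- NULL
  mcols(red)$member_ids <- methods::as(
    lapply(revmap, function(i) ids[i]), "CharacterList")
  mcols(red)$n_members <- lengths(revmap)
  red
}

#' Read a BED3/BED6 file as GRanges
#'
#' BED coordinates are 0-based half-open on disk and converted to the
#' 1-based closed convention of \code{GRanges}. A missing strand column
#' yields unstranded intervals. The \code{name} column, when present, is
#' kept as mcols \code{name}.
#'
#' @param path file path.
#' @return \code{GRanges}.
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e)
                   stop("malformed BED file '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  mcols(gr) <- mcols(gr)[intersect("name", colnames(mcols(gr)))]
  gr
}

#' Write GRanges to a BED file
#'
#' Inverse of \code{\link{readBed}}; round-tripping write-then-read is the
#' identity on coordinates, strand and names.
#'
#' @param gr \code{GRanges}; an mcols \code{name} column is written when
#'   present.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a full annotation bundle from a track configuration
#'
#' The configuration is a YAML (or already-parsed list) mapping track names
#' to file paths: \code{genes}, \code{exons}, \code{vlincs},
#' \code{promoters}, \code{insulators}, \code{ltr_repeats},
#' \code{rrna_repeats}, \code{est_5p}, and \code{tf_peaks} (a map
#' factor-name to path). \code{genes}/\code{vlincs}/\code{exons} come from
#' BED6 (exon names must match gene \code{tx_id}s); promoter BED names
#' encode the state as \code{state:cell_line} or a bare state.
#'
#' @param config path to a YAML file or a named list.
#' @param dir base directory for relative paths (defaults to the config
#'   file's directory).
#' @return an \code{\link{AnnotationBundle}}.
#' @export
readAnnotationBundle <- function(config, dir = NULL) {
  if (is.character(config)) {
    if (is.null(dir)) dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(dir)) dir <- "."
  pth <- function(p) if (file.exists(p)) p else file.path(dir, p)
  opt <- function(key) {
    if (is.null(config[[key]])) GRanges() else readBed(pth(config[[key]]))
  }
  genes <- opt("genes")
  if (length(genes)) {
    mcols(genes)$tx_id <- mcols(genes)$name
    mcols(genes)$name <- NULL
  }
  exons <- NULL
  if (!is.null(config$exons) && length(genes)) {
    ex <- readBed(pth(config$exons))
    exl <- GenomicRanges::split(granges(ex),
                                factor(mcols(ex)$name,
                                       levels = mcols(genes)$tx_id))
    exons <- exl
  }
  vlincs <- opt("vlincs")
  if (length(vlincs)) {
    mcols(vlincs)$vlinc_id <- mcols(vlincs)$name
    mcols(vlincs)$name <- NULL
  }
  promoters <- opt("promoters")
  if (length(promoters)) {
    nm <- mcols(promoters)$name
    if (is.null(nm)) nm <- rep("Active", length(promoters))
    parts <- strsplit(nm, ":", fixed = TRUE)
    mcols(promoters)$state <- vapply(parts, `[`, "", 1L)
    mcols(promoters)$cell_line <- vapply(parts, function(p)
      if (length(p) > 1L) p[2L] else NA_character_, "")
    mcols(promoters)$name <- NULL
  }
  tfp <- GRangesList()
  if (!is.null(config$tf_peaks)) {
    tfp <- GRangesList(lapply(config$tf_peaks, function(p) readBed(pth(p))))
  }
  AnnotationBundle(genes = genes, exons = exons, vlincs = vlincs,
                   promoters = promoters, insulators = opt("insulators"),
                   ltrRepeats = opt("ltr_repeats"),
                   rrnaRepeats = opt("rrna_repeats"),
                   tfPeaks = tfp, est5p = opt("est_5p"))
}

#' Write an annotation bundle as BED tracks plus a YAML config
#'
#' @param bundle an \code{\link{AnnotationBundle}}.
#' @param dir output directory (created if needed).
#' @return path of the written YAML config, invisibly.
#' @export
writeAnnotationBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list()
  putTrack <- function(gr, file, key, nameCol = NULL) {
    g <- granges(gr)
    if (!is.null(nameCol)) mcols(g)$name <- mcols(gr)[[nameCol]]
    writeBed(g, file.path(dir, file))
    cfg[[key]] <<- file
  }
  putTrack(geneBodies(bundle), "genes.bed", "genes", "tx_id")
  ex <- unlist(geneExons(bundle))
  if (length(ex)) {
    mcols(ex)$name <- rep(mcols(geneBodies(bundle))$tx_id,
                          lengths(geneExons(bundle)))
    writeBed(ex, file.path(dir, "exons.bed"))
    cfg$exons <- "exons.bed"
  }
  putTrack(vlincRanges(bundle), "vlincs.bed", "vlincs", "vlinc_id")
  pr <- promoterElements(bundle)
  if (length(pr)) {
    g <- granges(pr)
    cl <- mcols(pr)$cell_line
    if (is.null(cl)) cl <- rep(NA_character_, length(pr))
    mcols(g)$name <- ifelse(is.na(cl), mcols(pr)$state,
                            paste0(mcols(pr)$state, ":", cl))
    writeBed(g, file.path(dir, "promoters.bed"))
    cfg$promoters <- "promoters.bed"
  }
  for (trk in list(c("insulators", "insulators.bed"),
                   c("ltr_repeats", "ltr_repeats.bed"),
                   c("rrna_repeats", "rrna_repeats.bed"),
                   c("est_5p", "est_5p.bed"))) {
    gr <- switch(trk[1L], insulators = insulatorElements(bundle),
                 ltr_repeats = ltrRepeats(bundle),
                 rrna_repeats = rrnaRepeats(bundle),
                 est_5p = est5pEnds(bundle))
    if (length(gr)) {
      writeBed(granges(gr), file.path(dir, trk[2L]))
      cfg[[trk[1L]]] <- trk[2L]
    }
  }
  if (length(tfPeaks(bundle))) {
    cfg$tf_peaks <- list()
    for (f in names(tfPeaks(bundle))) {
      fn <- paste0("tf_", f, ".bed")
      writeBed(granges(tfPeaks(bundle)[[f]]), file.path(dir, fn))
      cfg$tf_peaks[[f]] <- fn
    }
  }
  out <- file.path(dir, "bundle.yaml")
  yaml::write_yaml(cfg, out)
  invisible(out)
}

# 5' coordinate of stranded features (start for +, end for -)
fivePrimePos <- function(gr) {
  ifelse(as.character(GenomicRanges::strand(gr)) == "-",
         GenomicRanges::end(gr), GenomicRanges::start(gr))
}

# 3' coordinate of stranded features
threePrimePos <- function(gr) {
  ifelse(as.character(GenomicRanges::strand(gr)) == "-",
         GenomicRanges::start(gr), GenomicRanges::end(gr))
}
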