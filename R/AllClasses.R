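#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges GRangesList granges
#' @importFrom GenomeInfoDb seqnames seqlengths seqlevels Seqinfo seqinfo
NULL

.VALID_STATES  <- c("Active", "Weak", "Poised")
.VALID_CLASSES <- c("normal", "cancer", "stem", "immortalized")
.VALID_KINDS   <- c("gene", "vlinc", "mirna")

#' TagSet: one sample's 5'-tag positions
#'
#' A \code{TagSet} holds the aligned 5'-end positions of capped tags for a
#' single biological sample, together with the sample's informative-read
#' total (uniquely aligned tags on the ordinary chromosomes, excluding
#' rRNA), which is the normalization denominator for RPKM values.
#'
#' Tags are stored as width-1 \code{GRanges} with an integer \code{count}
#' metadata column giving the multiplicity at that position; tags from
#' several sequencing channels of the same sample are expected to have been
#' summed before construction.
#'
#' @slot sampleId single character sample identifier.
#' @slot tags width-1 \code{GRanges} with mcols column \code{count}.
#' @slot informativeReads single non-negative number.
#'
#' @exportClass TagSet
setClass("TagSet",
  representation(
    sampleId = "character",
    tags = "GRanges",
    informativeReads = "numeric"
  )
)

setValidity("TagSet", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L)
    msg <- c(msg, "sampleId must be a single string")
  if (length(object@informativeReads) != 1L || object@informativeReads < 0)
    msg <- c(msg, "informativeReads must be a single non-negative number")
  if (length(object@tags)) {
    if (!all(GenomicRanges::width(object@tags) == 1L))
      msg <- c(msg, "tags must be width-1 (5' positions)")
    cnt <- mcols(object@tags)$count
    if (is.null(cnt) || any(cnt < 1))
      msg <- c(msg, "tags must carry a 'count' column with multiplicities >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TagSet
#'
#' @param sampleId sample identifier.
#' @param tags width-1 \code{GRanges} of tag 5' positions; a \code{count}
#'   column is added (all 1) when absent, and duplicate positions are
#'   aggregated.
#' @param informativeReads informative-read total for the sample.
#' @return a \code{TagSet}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(5, 5, 9), width = 1),
#'                              strand = c("+", "+", "-"))
#' ts <- TagSet("s1", gr, informativeReads = 3)
#' @export
TagSet <- function(sampleId, tags = GRanges(), informativeReads = 0) {
  if (length(tags) && is.null(mcols(tags)$count))
    mcols(tags)$count <- rep(1L, length(tags))
  if (length(tags)) {
    key <- paste0(seqnames(tags), ":", GenomicRanges::start(tags), ":",
                  GenomicRanges::strand(tags))
    if (anyDuplicated(key)) {
      agg <- rowsum(as.numeric(mcols(tags)$count), key, reorder = FALSE)
      keep <- !duplicated(key)
      tags <- tags[keep]
      mcols(tags)$count <- as.integer(agg[match(key[keep], rownames(agg)), 1L])
    }
    tags <- GenomicRanges::sort(tags, ignore.strand = TRUE)
  }
  new("TagSet", sampleId = as.character(sampleId), tags = tags,
      informativeReads = as.numeric(informativeReads))
}

#' @describeIn TagSet sample identifier accessor
#' @param object a \code{TagSet}.
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @export
setMethod("sampleId", "TagSet", function(object) object@sampleId)

#' @describeIn TagSet tag positions accessor
#' @export
setGeneric("tagPositions", function(object) standardGeneric("tagPositions"))
#' @export
setMethod("tagPositions", "TagSet", function(object) object@tags)

#' @describeIn TagSet informative-read total accessor
#' @export
setGeneric("informativeReads", function(object) standardGeneric("informativeReads"))
#' @export
setMethod("informativeReads", "TagSet", function(object) object@informativeReads)

setMethod("show", "TagSet", function(object) {
  cat("TagSet '", object@sampleId, "': ",
      length(object@tags), " tag positions, ",
      sum(mcols(object@tags)$count), " tags, ",
      format(object@informativeReads, big.mark = ","),
      " informative reads\n", sep = "")
})

#' AnnotationBundle: all annotation tracks the pipeline consumes
#'
#' Container for the genomic annotation used throughout the analysis:
#' transcript models for known genes (bodies plus exons), vlincRNA
#' intervals, chromatin-state promoter elements, insulator elements, LTR
#' and rRNA repeats, transcription-factor ChIP-seq peaks and EST 5'-end
#' positions. All coordinates are \code{GRanges} (1-based closed, the
#' native Bioconductor convention); BED input/output converts at the
#' boundary.
#'
#' @slot genes \code{GRanges} of gene bodies, with mcols \code{tx_id}.
#' @slot exons \code{GRangesList} parallel to \code{genes} (exons per gene,
#'   sorted, non-overlapping, contained in the body).
#' @slot vlincs \code{GRanges} of vlincRNA intervals with mcols \code{vlinc_id}.
#' @slot promoters \code{GRanges} (unstranded) with mcols \code{state} in
#'   Active/Weak/Poised and \code{cell_line}.
#' @slot insulators,ltrRepeats,rrnaRepeats,est5p \code{GRanges} tracks.
#' @slot tfPeaks named \code{GRangesList}, one element per factor.
#'
#' @exportClass AnnotationBundle
setClass("AnnotationBundle",
  contains = "Annotated",
  representation(
    genes = "GRanges",
    exons = "GRangesList",
    vlincs = "GRanges",
    promoters = "GRanges",
    insulators = "GRanges",
    ltrRepeats = "GRanges",
    rrnaRepeats = "GRanges",
    tfPeaks = "GRangesList",
    est5p = "GRanges"
  )
)

setValidity("AnnotationBundle", function(object) {
  msg <- character()
  if (is.null(mcols(object@genes)$tx_id))
    msg <- c(msg, "genes must carry a 'tx_id' column")
  if (length(object@exons) != length(object@genes))
    msg <- c(msg, "exons must be parallel to genes")
  if (is.null(mcols(object@vlincs)$vlinc_id))
    msg <- c(msg, "vlincs must carry a 'vlinc_id' column")
  st <- mcols(object@promoters)$state
  if (length(object@promoters) &&
      (is.null(st) || !all(st %in% .VALID_STATES)))
    msg <- c(msg, "promoter states must be Active/Weak/Poised")
  if (length(object@exons)) {
    within <- all(unlist(GenomicRanges::start(object@exons)) >=
                    rep(GenomicRanges::start(object@genes),
                        lengths(object@exons))) &&
              all(unlist(GenomicRanges::end(object@exons)) <=
                    rep(GenomicRanges::end(object@genes),
                        lengths(object@exons)))
    if (!within) msg <- c(msg, "every exon must lie inside its gene body")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotationBundle
#'
#' @param genes gene bodies (\code{GRanges} with \code{tx_id}).
#' @param exons \code{GRangesList} of exons per gene (empty list elements
#'   allowed); defaults to whole bodies as single exons.
#' @param vlincs vlincRNA intervals (\code{GRanges} with \code{vlinc_id}).
#' @param promoters,insulators,ltrRepeats,rrnaRepeats,est5p annotation tracks.
#' @param tfPeaks named \code{GRangesList} of ChIP-seq peaks per factor.
#' @return an \code{AnnotationBundle}.
#' @export
AnnotationBundle <- function(genes = GRanges(), exons = NULL,
                             vlincs = GRanges(), promoters = GRanges(),
                             insulators = GRanges(), ltrRepeats = GRanges(),
                             rrnaRepeats = GRanges(), tfPeaks = GRangesList(),
                             est5p = GRanges()) {
  if (length(genes) && is.null(mcols(genes)$tx_id))
    mcols(genes)$tx_id <- paste0("tx", seq_along(genes))
  if (length(vlincs) && is.null(mcols(vlincs)$vlinc_id))
    mcols(vlincs)$vlinc_id <- paste0("vlinc", seq_along(vlincs))
  if (is.null(exons))
    exons <- methods::as(granges(genes), "GRangesList")
  if (length(promoters) && is.null(mcols(promoters)$state))
    mcols(promoters)$state <- rep("Active", length(promoters))
  new("AnnotationBundle", genes = genes, exons = exons, vlincs = vlincs,
      promoters = promoters, insulators = insulators,
      ltrRepeats = ltrRepeats, rrnaRepeats = rrnaRepeats,
      tfPeaks = tfPeaks, est5p = est5p)
}

#' @describeIn AnnotationBundle gene bodies
#' @param object an \code{AnnotationBundle}.
#' @export
setGeneric("geneBodies", function(object) standardGeneric("geneBodies"))
#' @export
setMethod("geneBodies", "AnnotationBundle", function(object) object@genes)

#' @describeIn AnnotationBundle exons per gene
#' @export
setGeneric("geneExons", function(object) standardGeneric("geneExons"))
#' @export
setMethod("geneExons", "AnnotationBundle", function(object) object@exons)

#' @describeIn AnnotationBundle vlincRNA intervals
#' @export
setGeneric("vlincRanges", function(object) standardGeneric("vlincRanges"))
#' @export
setMethod("vlincRanges", "AnnotationBundle", function(object) object@vlincs)

#' @describeIn AnnotationBundle promoter elements
#' @export
setGeneric("promoterElements", function(object) standardGeneric("promoterElements"))
#' @export
setMethod("promoterElements", "AnnotationBundle", function(object) object@promoters)

#' @describeIn AnnotationBundle insulator elements
#' @export
setGeneric("insulatorElements", function(object) standardGeneric("insulatorElements"))
#' @export
setMethod("insulatorElements", "AnnotationBundle", function(object) object@insulators)

#' @describeIn AnnotationBundle LTR repeats
#' @export
setGeneric("ltrRepeats", function(object) standardGeneric("ltrRepeats"))
#' @export
setMethod("ltrRepeats", "AnnotationBundle", function(object) object@ltrRepeats)

#' @describeIn AnnotationBundle rRNA repeats
#' @export
setGeneric("rrnaRepeats", function(object) standardGeneric("rrnaRepeats"))
#' @export
setMethod("rrnaRepeats", "AnnotationBundle", function(object) object@rrnaRepeats)

#' @describeIn AnnotationBundle TF ChIP-seq peaks per factor
#' @export
setGeneric("tfPeaks", function(object) standardGeneric("tfPeaks"))
#' @export
setMethod("tfPeaks", "AnnotationBundle", function(object) object@tfPeaks)

#' @describeIn AnnotationBundle EST 5'-end positions
#' @export
setGeneric("est5pEnds", function(object) standardGeneric("est5pEnds"))
#' @export
setMethod("est5pEnds", "AnnotationBundle", function(object) object@est5p)

setMethod("show", "AnnotationBundle", function(object) {
  cat("AnnotationBundle\n")
  cat("  genes:      ", length(object@genes), "\n")
  cat("  vlincs:     ", length(object@vlincs), "\n")
  cat("  promoters:  ", length(object@promoters), "\n")
  cat("  insulators: ", length(object@insulators), "\n")
  cat("  LTR repeats:", length(object@ltrRepeats),
      " rRNA repeats:", length(object@rrnaRepeats), "\n")
  if (length(object@tfPeaks))
    cat("  TF peaks:   ",
        paste(names(object@tfPeaks), lengths(object@tfPeaks),
              sep = "=", collapse = ", "), "\n")
})

#' VlincExperiment: RPKM expression matrix with feature metadata
#'
#' Thin extension of \code{SummarizedExperiment} holding an \code{rpkm}
#' assay of non-negative values, with per-feature \code{kind}
#' (gene/vlinc/mirna) and \code{effectiveLength} (masked length used as the
#' RPKM denominator) in the rowData, and sample class metadata in colData.
#'
#' @exportClass VlincExperiment
setClass("VlincExperiment", contains = "SummarizedExperiment")

setValidity("VlincExperiment", function(object) {
  msg <- character()
  if (!"rpkm" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'rpkm' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("kind", "effectiveLength") %in% colnames(rd))) {
    msg <- c(msg, "rowData must contain 'kind' and 'effectiveLength'")
  } else {
    if (!all(rd$kind %in% .VALID_KINDS))
      msg <- c(msg, "kind must be one of gene/vlinc/mirna")
    if (any(rd$effectiveLength <= 0))
      msg <- c(msg, "effectiveLength must be > 0 for retained features")
  }
  a <- SummarizedExperiment::assay(object, "rpkm")
  if (length(a) && (any(!is.finite(a)) || any(a < 0)))
    msg <- c(msg, "rpkm values must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a VlincExperiment
#'
#' @param rpkm numeric matrix (features x samples), finite, non-negative.
#' @param kind character vector per feature, in gene/vlinc/mirna.
#' @param effectiveLength positive numeric vector per feature.
#' @param colData optional \code{DataFrame} of sample metadata.
#' @return a \code{VlincExperiment}.
#' @export
VlincExperiment <- function(rpkm, kind, effectiveLength, colData = NULL) {
  rd <- DataFrame(kind = kind, effectiveLength = effectiveLength,
                  row.names = rownames(rpkm))
  args <- list(assays = list(rpkm = rpkm), rowData = rd)
  if (!is.null(colData)) args$colData <- colData
  se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
  new("VlincExperiment", se)
}

#' @describeIn VlincExperiment the RPKM assay matrix
#' @param object a \code{VlincExperiment}.
#' @export
setGeneric("rpkmValues", function(object) standardGeneric("rpkmValues"))
#' @export
setMethod("rpkmValues", "VlincExperiment",
          function(object) SummarizedExperiment::assay(object, "rpkm"))

#' @describeIn VlincExperiment feature kinds
#' @export
setGeneric("featureKind", function(object) standardGeneric("featureKind"))
#' @export
setMethod("featureKind", "VlincExperiment", function(object)
  SummarizedExperiment::rowData(object)$kind)

#' @describeIn VlincExperiment effective (masked) feature lengths
#' @export
setGeneric("effectiveLengths", function(object) standardGeneric("effectiveLengths"))
#' @export
setMethod("effectiveLengths", "VlincExperiment", function(object)
  SummarizedExperiment::rowData(object)$effectiveLength)
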