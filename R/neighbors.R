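.CONFIGS <- c("same_upstream", "same_downstream",
              "opposite_tail_to_tail", "opposite_head_to_head")
.BIN_BREAKS <- c(-1, 999, 4999, 9999, 19999, 29999, 39999, 49999, Inf)
.BIN_LABELS <- c("0-1kb", "1-5kb", "5-10kb", "10-20kb", "20-30kb",
                 "30-40kb", "40-50kb", ">50kb")

#' Classify a neighbor pair's configuration, distance and bin
#'
#' Same-strand pairs are "same_upstream" or "same_downstream" according to
#' whether the gene lies 5' or 3' of the reference feature in the
#' feature's orientation. Opposite-strand pairs are "opposite_head_to_head"
#' when the facing 5' ends are the nearer pair of ends (ties break toward
#' head-to-head) and "opposite_tail_to_tail" otherwise. Distance is the
#' base-pair gap between the nearest transcript ends; overlapping pairs
#' get distance 0 and the 0-1 kb bin.
#'
#' @param a stranded reference features (\code{GRanges}).
#' @param b neighbor genes (\code{GRanges}, parallel to \code{a}).
#' @return data.frame: \code{configuration}, \code{distance}, \code{bin}.
#' @export
classifyPair <- function(a, b) {
  stopifnot(length(a) == length(b))
  achr <- as.character(seqnames(a)); bchr <- as.character(seqnames(b))
  if (any(achr != bchr)) stop("pairs must be on the same chromosome")
  astr <- as.character(GenomicRanges::strand(a))
  bstr <- as.character(GenomicRanges::strand(b))
  if (any(astr == "*")) stop("reference features must have resolved strand")
  as_ <- GenomicRanges::start(a); ae <- GenomicRanges::end(a)
  bs <- GenomicRanges::start(b); be <- GenomicRanges::end(b)
  distance <- pmax(0L, pmax(as_, bs) - pmin(ae, be) - 1L)
  a5 <- fivePrimePos(a); a3 <- threePrimePos(a)
  b5 <- fivePrimePos(b); b3 <- threePrimePos(b)
  same <- astr == bstr
  # same strand: gene 5' vs 3' of a, in a's orientation
  bDownstream <- ifelse(astr == "+", b5 >= a5, b5 <= a5)
  dHead <- abs(a5 - b5); dTail <- abs(a3 - b3)
  configuration <- ifelse(same,
                          ifelse(bDownstream, "same_downstream",
                                 "same_upstream"),
                          ifelse(dHead <= dTail, "opposite_head_to_head",
                                 "opposite_tail_to_tail"))
  bin <- as.character(cut(distance, breaks = .BIN_BREAKS,
                          labels = .BIN_LABELS))
  data.frame(configuration = configuration, distance = distance, bin = bin,
             stringsAsFactors = FALSE)
}

#' Enumerate neighbor pairs within a horizon
#'
#' For every reference feature, collects all genes whose body-to-body gap
#' is at most \code{maxGap}, classifies each pair, and flags insulator
#' separation. Self-pairs (identical id) are excluded so the same gene set
#' can serve as both sides of gene-gene analysis. A feature at a
#' chromosome edge simply lacks pairs on that side.
#'
#' @param features stranded reference \code{GRanges} (id in first mcols
#'   column).
#' @param genes neighbor gene \code{GRanges} (id in first mcols column).
#' @param insulators insulator \code{GRanges} (may be empty).
#' @param maxGap pairing horizon in bp (default 1e5); pairs further apart
#'   are not tabulated.
#' @return data.frame: \code{a_id}, \code{b_id}, \code{configuration},
#'   \code{distance}, \code{bin}, \code{insulator_separated}.
#' @export
neighborPairs <- function(features, genes, insulators = GRanges(),
                          maxGap = 1e5) {
  aIds <- as.character(mcols(features)[[1L]])
  bIds <- as.character(mcols(genes)[[1L]])
  hit <- GenomicRanges::findOverlaps(features, genes, maxgap = maxGap,
                                     ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hit); s <- S4Vectors::subjectHits(hit)
  keep <- aIds[q] != bIds[s]
  q <- q[keep]; s <- s[keep]
  if (!length(q))
    return(data.frame(a_id = character(0), b_id = character(0),
                      configuration = character(0), distance = integer(0),
                      bin = character(0), insulator_separated = logical(0)))
  cls <- classifyPair(features[q], genes[s])
  sep <- separatedByInsulator(features[q], genes[s], insulators)
  data.frame(a_id = aIds[q], b_id = bIds[s], cls,
             insulator_separated = sep, stringsAsFactors = FALSE)
}

#' Two-stage median correlation table by configuration, bin and stratum
#'
#' Computes the Spearman correlation of expression for every pair, then
#' aggregates in two stages: for each reference feature and (configuration,
#' bin) cell the median over its own neighbor genes, and across features
#' the median of those per-feature medians. Cells are stratified by
#' insulator separation (\code{all} / \code{separated} /
#' \code{not_separated}). Not-computable correlations (constant
#' expression) are dropped; pairs where both members are all-zero are
#' additionally counted per cell.
#'
#' @param expr a \code{\link{VlincExperiment}} (or plain matrix with
#'   feature rownames).
#' @param pairs a \code{\link{neighborPairs}} data.frame.
#' @param pairType label stored in the output (e.g. "vlinc_gene").
#' @param minPairs minimum pairs per cell for reporting a median
#'   (default 3).
#' @return data.frame: \code{pair_type}, \code{configuration}, \code{bin},
#'   \code{stratum}, \code{median_rho}, \code{n_pairs}, \code{n_features},
#'   \code{n_zero_pairs}.
#' @export
correlationTable <- function(expr, pairs, pairType = "vlinc_gene",
                             minPairs = 3L) {
  m <- if (is(expr, "VlincExperiment")) rpkmValues(expr) else expr
  pairs <- pairs[pairs$a_id %in% rownames(m) & pairs$b_id %in% rownames(m), ]
  pairs$rho <- pairRho(m, pairs$a_id, pairs$b_id)
  pairs$zero <- apply(m[pairs$a_id, , drop = FALSE] != 0, 1L, sum) == 0 &
    apply(m[pairs$b_id, , drop = FALSE] != 0, 1L, sum) == 0
  grid <- expand.grid(configuration = .CONFIGS, bin = .BIN_LABELS,
                      stratum = c("all", "separated", "not_separated"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sel <- pairs$configuration == g$configuration & pairs$bin == g$bin
    if (g$stratum == "separated") sel <- sel & pairs$insulator_separated
    if (g$stratum == "not_separated") sel <- sel & !pairs$insulator_separated
    p <- pairs[sel, ]
    ok <- !is.na(p$rho)
    med <- NA_real_
    if (sum(ok) >= 1L && nrow(p) >= minPairs) {
      perFeature <- tapply(p$rho[ok], p$a_id[ok], stats::median)
      med <- stats::median(perFeature)
    }
    data.frame(pair_type = pairType, configuration = g$configuration,
               bin = g$bin, stratum = g$stratum, median_rho = med,
               n_pairs = nrow(p), n_features = length(unique(p$a_id)),
               n_zero_pairs = sum(p$zero), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spearman correlation for explicit feature pairs
#'
#' @param m expression matrix with feature rownames.
#' @param aIds,bIds parallel id vectors.
#' @return numeric vector of correlations (NA where not computable).
#' @export
pairRho <- function(m, aIds, bIds) {
  vapply(seq_along(aIds), function(i)
    spearmanRho(m[aIds[i], ], m[bIds[i], ]), 0)
}

#' Compare two groups of pair correlations
#'
#' One-sided test that group A's correlations are stochastically larger
#' (the contrast used to compare vlincRNA-gene with gene-gene pairs).
#'
#' @param rhosA,rhosB numeric vectors of correlations (NAs dropped).
#' @param test \code{"mww"} or \code{"ks"}.
#' @return list: \code{p}, \code{nA}, \code{nB}, \code{direction}.
#' @export
comparePairGroups <- function(rhosA, rhosB, test = c("mww", "ks")) {
  test <- match.arg(test)
  rhosA <- rhosA[!is.na(rhosA)]; rhosB <- rhosB[!is.na(rhosB)]
  res <- if (test == "mww") mwwOneSided(rhosA, rhosB, "a_greater")
         else ksOneSided(rhosA, rhosB, "a_greater")
  list(p = res$p, nA = length(rhosA), nB = length(rhosB),
       direction = "A_greater")
}
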