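#' Build a small synthetic GO-like ontology
#'
#' A three-level directed acyclic graph: one root (excluded from testing),
#' \code{nLevel1} children and \code{nLevel2} grandchildren, each
#' grandchild attached to one level-1 parent. Used to exercise the
#' two-level enrichment machinery on fixtures; a real ontology can be
#' supplied in the same parent-map form.
#'
#' @param nLevel1,nLevel2 term counts per level.
#' @param seed integer seed for parent assignment.
#' @return list: \code{parents} (named character vector term -> parent,
#'   root maps to NA), \code{root}, \code{terms} (all non-root ids).
#' @export
syntheticOntology <- function(nLevel1 = 7L, nLevel2 = 42L, seed = 1L) {
  set.seed(seed)
  l1 <- sprintf("GO:L1_%02d", seq_len(nLevel1))
  l2 <- sprintf("GO:L2_%02d", seq_len(nLevel2))
  parents <- c(stats::setNames(NA_character_, "GO:ROOT"),
               stats::setNames(rep("GO:ROOT", nLevel1), l1),
               stats::setNames(sample(l1, nLevel2, replace = TRUE), l2))
  list(parents = parents, root = "GO:ROOT", terms = c(l1, l2))
}

#' Ancestor closure of term sets
#'
#' Every term implies all of its ancestors up to (and excluding) the root.
#'
#' @param termSets list of character vectors of term ids.
#' @param ontology a \code{\link{syntheticOntology}}-style list.
#' @return list of closed term sets (root never included).
#' @export
ancestorClosure <- function(termSets, ontology) {
  up <- function(t) {
    out <- character(0)
    while (!is.na(t) && t != ontology$root) {
      out <- c(out, t)
      t <- ontology$parents[[t]]
    }
    out
  }
  lapply(termSets, function(ts) unique(unlist(lapply(ts, up))))
}

#' Random ancestor-closed gene-to-term annotation
#'
#' Assigns each gene one or more leaf-level terms and closes over
#' ancestors, yielding the \code{gene -> term set} map the enrichment
#' operations consume.
#'
#' @param geneIds character vector.
#' @param ontology a \code{\link{syntheticOntology}} result.
#' @param termsPerGene expected direct annotations per gene (default 2).
#' @param seed integer seed.
#' @return named list gene id -> character vector of terms (closed).
#' @export
makeGeneGoMap <- function(geneIds, ontology, termsPerGene = 2L, seed = 1L) {
  set.seed(seed)
  leaves <- setdiff(ontology$terms, unique(stats::na.omit(ontology$parents)))
  direct <- lapply(geneIds, function(g)
    sample(leaves, max(1L, stats::rpois(1, termsPerGene)), replace = FALSE))
  names(direct) <- geneIds
  ancestorClosure(direct, ontology)
}

#' Genes correlating / anti-correlating with a vlincRNA gene
#'
#' Partitions genes by their Spearman correlation with the vlincRNA gene's
#' expression across all samples: correlating at rho >= threshold,
#' anti-correlating at rho <= -threshold (boundary values included).
#' Not-computable correlations are dropped.
#'
#' @param expr matrix or \code{\link{VlincExperiment}}.
#' @param vlincGeneId row id of the vlincRNA gene.
#' @param geneIds candidate gene row ids.
#' @param threshold correlation threshold (default 0.35).
#' @return list: \code{pos}, \code{neg} (character vectors), \code{rho}
#'   (named vector over geneIds).
#' @export
correlatedGeneSets <- function(expr, vlincGeneId, geneIds,
                               threshold = 0.35) {
  m <- if (is(expr, "VlincExperiment")) rpkmValues(expr) else expr
  rho <- spearmanRows(m[geneIds, , drop = FALSE], m[vlincGeneId, ])
  names(rho) <- geneIds
  list(pos = geneIds[!is.na(rho) & rho >= threshold],
       neg = geneIds[!is.na(rho) & rho <= -threshold],
       rho = rho)
}

#' First-level GO terms of one gene set
#'
#' Hypergeometric enrichment of the gene set against the expressed-gene
#' universe, term by term (root excluded); terms below the unadjusted
#' p-value cut are recorded as associated with the vlincRNA gene.
#'
#' @param geneSet character vector of gene ids.
#' @param geneGo named list gene -> term set (ancestor-closed).
#' @param universe character vector of universe gene ids.
#' @param pCut unadjusted p-value threshold (default 0.05).
#' @return character vector of recorded term ids.
#' @export
perVlincGoTerms <- function(geneSet, geneGo, universe, pCut = 0.05) {
  geneSet <- intersect(geneSet, universe)
  if (!length(geneSet)) return(character(0))
  termGenes <- termToGenes(geneGo, universe)
  N <- length(universe); n <- length(geneSet)
  keep <- character(0)
  for (t in names(termGenes)) {
    K <- length(termGenes[[t]])
    k <- length(intersect(geneSet, termGenes[[t]]))
    if (k == 0L) next
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    if (p < pCut) keep <- c(keep, t)
  }
  keep
}

# invert a gene->terms map over a universe
termToGenes <- function(geneGo, universe) {
  gg <- geneGo[intersect(names(geneGo), universe)]
  if (!length(gg)) return(list())
  long <- data.frame(gene = rep(names(gg), lengths(gg)),
                     term = unlist(gg, use.names = FALSE))
  split(long$gene, long$term)
}

#' Build per-vlincRNA-gene GO profiles
#'
#' For each vlincRNA gene: find correlating and anti-correlating gene
#' sets, record their first-level enriched terms separately (the
#' positively and negatively associated term lists may overlap).
#'
#' @param expr matrix or \code{\link{VlincExperiment}}.
#' @param vlincGeneIds row ids of the vlincRNA genes.
#' @param geneGo gene -> term map.
#' @param threshold correlation threshold (default 0.35).
#' @param pCut first-level p threshold (default 0.05).
#' @return named list vlinc gene id -> list(pos = terms, neg = terms).
#' @export
vlincGoProfiles <- function(expr, vlincGeneIds, geneGo, threshold = 0.35,
                            pCut = 0.05) {
  m <- if (is(expr, "VlincExperiment")) rpkmValues(expr) else expr
  universe <- intersect(names(geneGo), rownames(m))
  universe <- universe[rowSums(m[universe, , drop = FALSE] != 0) > 0]
  out <- lapply(vlincGeneIds, function(v) {
    cs <- correlatedGeneSets(m, v, universe, threshold)
    list(pos = perVlincGoTerms(cs$pos, geneGo, universe, pCut),
         neg = perVlincGoTerms(cs$neg, geneGo, universe, pCut))
  })
  names(out) <- vlincGeneIds
  out
}

#' Second-level enrichment of vlincRNA subsets over profile annotations
#'
#' Treats the recorded term lists as a custom annotation of the vlincRNA
#' genes and tests, term by term, whether a subset of vlincRNA genes
#' carries the term more often than the full annotated background, with
#' BH-FDR adjustment. Rows report ExpCount (background rate times subset
#' size), Count (observed subset carriers) and Size (background carriers).
#'
#' @param profiles \code{\link{vlincGoProfiles}} output.
#' @param subsetIds vlincRNA gene ids of the subset (must be contained in
#'   the background).
#' @param backgroundIds background ids (default: all profiled).
#' @param sign \code{"pos"} or \code{"neg"} term lists.
#' @return data.frame: term, p_raw, p_adj, ExpCount, Count, Size, ordered
#'   by p_raw.
#' @export
subsetEnrichment <- function(profiles, subsetIds,
                             backgroundIds = names(profiles),
                             sign = c("pos", "neg")) {
  sign <- match.arg(sign)
  if (!all(subsetIds %in% backgroundIds))
    stop("subset must be contained in the background")
  if (!length(subsetIds))
    return(data.frame(term = character(0), p_raw = numeric(0),
                      p_adj = numeric(0), ExpCount = numeric(0),
                      Count = integer(0), Size = integer(0)))
  bgTerms <- lapply(profiles[backgroundIds], `[[`, sign)
  terms <- sort(unique(unlist(bgTerms)))
  B <- length(backgroundIds); S <- length(subsetIds)
  inSubset <- backgroundIds %in% subsetIds
  rows <- lapply(terms, function(t) {
    has <- vapply(bgTerms, function(x) t %in% x, TRUE)
    Size <- sum(has)
    Count <- sum(has & inSubset)
    p <- stats::phyper(Count - 1, Size, B - Size, S, lower.tail = FALSE)
    data.frame(term = t, p_raw = p, ExpCount = S * Size / B,
               Count = Count, Size = Size, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(0), p_raw = numeric(0),
                      p_adj = numeric(0), ExpCount = numeric(0),
                      Count = integer(0), Size = integer(0)))
  out$p_adj <- bhAdjust(out$p_raw)
  out[order(out$p_raw), c("term", "p_raw", "p_adj", "ExpCount",
                          "Count", "Size")]
}

#' Interval-overlap enrichment with intergenic correction
#'
#' Two significance computations for the overlap of interval set A (e.g.
#' vlincRNA genes) with set B (e.g. an external transcript catalog):
#' (i) a genome-wide Fisher test on base-level overlap, which assumes A is
#' distributed over the whole sequenced genome; and (ii) an upper-bound
#' binomial correction for sets confined to intergenic space: the expected
#' number of A intervals overlapping B under uniform intergenic placement
#' (E, computable from B's intergenic footprint and each A interval's
#' length, or supplied directly) is added to the directly counted genic
#' overlaps g, giving per-trial success probability (E + g) / |A|, and the
#' observed total overlap count is tested against Binomial(|A|, p).
#'
#' @param setA,setB \code{GRanges}.
#' @param genomeLength total genome length in bp.
#' @param intergenic \code{GRanges} of intergenic space.
#' @param expectedIntergenic optional externally computed E; when NULL, E
#'   is the sum over A of min(1, (footprintB_intergenic + width_i) /
#'   intergenic_length).
#' @return list: \code{fisher_p}, \code{binomial_p}, \code{observed},
#'   \code{expected_intergenic}, \code{genic_overlaps}, \code{p_success}.
#' @export
intervalOverlapEnrichment <- function(setA, setB, genomeLength, intergenic,
                                      expectedIntergenic = NULL) {
  interLen <- sum(GenomicRanges::width(GenomicRanges::reduce(
    intergenic, ignore.strand = TRUE)))
  if (interLen <= max(GenomicRanges::width(setA)))
    stop("intergenic space shorter than the longest interval")
  ovlBases <- sum(GenomicRanges::width(GenomicRanges::intersect(
    GenomicRanges::reduce(setA, ignore.strand = TRUE),
    GenomicRanges::reduce(setB, ignore.strand = TRUE),
    ignore.strand = TRUE)))
  aBases <- sum(GenomicRanges::width(GenomicRanges::reduce(
    setA, ignore.strand = TRUE)))
  bBases <- sum(GenomicRanges::width(GenomicRanges::reduce(
    setB, ignore.strand = TRUE)))
  fisherP <- fisherOneSided(ovlBases, aBases - ovlBases,
                            bBases - ovlBases,
                            max(0, genomeLength - aBases - bBases + ovlBases))
  observed <- sum(GenomicRanges::countOverlaps(setA, setB,
                                               ignore.strand = TRUE) > 0)
  genic <- GenomicRanges::setdiff(
    GRanges(GenomeInfoDb::seqnames(GenomicRanges::reduce(setB)),
            IRanges(GenomicRanges::start(GenomicRanges::reduce(setB)),
                    GenomicRanges::end(GenomicRanges::reduce(setB)))),
    intergenic, ignore.strand = TRUE)
  g <- sum(GenomicRanges::countOverlaps(setA, genic,
                                        ignore.strand = TRUE) > 0)
  E <- if (!is.null(expectedIntergenic)) expectedIntergenic else {
    bInter <- sum(GenomicRanges::width(GenomicRanges::intersect(
      GenomicRanges::reduce(setB, ignore.strand = TRUE), intergenic,
      ignore.strand = TRUE)))
    sum(pmin(1, (bInter + GenomicRanges::width(setA)) / interLen))
  }
  pSucc <- min(1, (E + g) / length(setA))
  list(fisher_p = fisherP,
       binomial_p = binomialUpperTail(length(setA), observed, pSucc),
       observed = observed, expected_intergenic = E, genic_overlaps = g,
       p_success = pSucc)
}
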