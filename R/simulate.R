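#' Simulation configuration for the synthetic fixture world
#'
#' Builds the parameter set for the synthetic-data generator. The defaults
#' describe a compact genome (4 chromosomes of 15 Mb) carrying 220 genes
#' and 80 vlincRNAs observed in 60 samples whose class composition mirrors
#' the proportions of the real compendium (normal / cancer / pluripotent /
#' immortalized roughly 48:40:11:1), plus one embryonic-stem
#' differentiation time course. The neighbor plan places vlincRNA-gene and
#' gene-gene pairs in all four genomic configurations with and without
#' insulator separation and plants their rank correlations.
#'
#' @param seed integer root seed; every stage derives its own substream.
#' @param nChrom,chromLength genome geometry.
#' @param nGenes,nVlincs feature counts (includes plan features).
#' @param vlincLengthRange uniform length range for vlincRNAs (bp); the
#'   default midpoint is ~83 kb, the field's reported median length.
#' @param geneLengthRange uniform gene-body length range (bp).
#' @param nSamples named counts per class (normal/cancer/stem/immortalized).
#' @param neighborPlan data.frame with columns \code{pair_type}
#'   (vlinc_gene/gene_gene), \code{configuration}, \code{distance} (bp gap),
#'   \code{insulator} (logical), \code{target_rho}, \code{n} (replicates).
#' @param promoterFraction fraction of vlincRNAs assigned a promoter.
#' @param ltrFraction fraction of promoter-bearing vlincRNAs whose promoter
#'   overlaps an LTR repeat (0.36, the reported 611/1702).
#' @param tfFraction fraction of promoter-bearing vlincRNAs whose promoter
#'   carries peaks for all three pluripotency factors.
#' @param cancerEffect multiplicative boost applied to LTR-vlincRNA
#'   abundance in cancer and stem samples (1 = null).
#' @param timecourse list: \code{n_points}, \code{tf_coupling_rho} (target
#'   Spearman of LTR/TF-bound vlincRNAs with the factors along the course).
#' @param mirnaPlan list: \code{n_mirnas}, \code{targets_per_mirna},
#'   \code{target_rho} (negative coupling to validated targets).
#' @param tagDepth expected informative tags per sample.
#' @param fivePrimePeakFraction fraction of a feature's tags concentrated
#'   in the first 500 bp downstream of its 5' end.
#' @param antisenseRate probability a tag is emitted on the wrong strand.
#' @param backgroundRate background (intergenic) tag mass as a fraction of
#'   \code{tagDepth}.
#' @param meanlog,sdlog log-normal marginal parameters for true abundances.
#' @return a list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1L,
                             nChrom = 4L, chromLength = 1.5e7,
                             nGenes = 220L, nVlincs = 80L,
                             vlincLengthRange = c(50e3, 116e3),
                             geneLengthRange = c(5e3, 40e3),
                             nSamples = c(normal = 29L, cancer = 24L,
                                          stem = 6L, immortalized = 1L),
                             neighborPlan = defaultNeighborPlan(),
                             promoterFraction = 0.45,
                             ltrFraction = 0.36,
                             tfFraction = 0.4,
                             cancerEffect = 2,
                             timecourse = list(n_points = 16L,
                                               tf_coupling_rho = 0.8),
                             mirnaPlan = list(n_mirnas = 8L,
                                              targets_per_mirna = 10L,
                                              target_rho = -0.4),
                             tagDepth = 3e4,
                             fivePrimePeakFraction = 0.5,
                             antisenseRate = 0.01,
                             backgroundRate = 0.1,
                             meanlog = 1, sdlog = 1) {
  stopifnot(nChrom > 0, chromLength > 0, nGenes > 0, nVlincs > 0,
            all(nSamples >= 0), sum(nSamples) > 0,
            abs(neighborPlan$target_rho) <= 1,
            promoterFraction >= 0, promoterFraction <= 1,
            ltrFraction >= 0, ltrFraction <= 1,
            tfFraction >= 0, tfFraction <= 1,
            cancerEffect > 0,
            fivePrimePeakFraction >= 0, fivePrimePeakFraction <= 1,
            antisenseRate >= 0, antisenseRate <= 1,
            abs(mirnaPlan$target_rho) <= 1,
            abs(timecourse$tf_coupling_rho) <= 1)
  cfg <- list(seed = as.integer(seed), nChrom = nChrom,
              chromLength = chromLength, nGenes = nGenes, nVlincs = nVlincs,
              vlincLengthRange = vlincLengthRange,
              geneLengthRange = geneLengthRange,
              nSamples = nSamples, neighborPlan = neighborPlan,
              promoterFraction = promoterFraction,
              ltrFraction = ltrFraction, tfFraction = tfFraction,
              cancerEffect = cancerEffect, timecourse = timecourse,
              mirnaPlan = mirnaPlan, tagDepth = tagDepth,
              fivePrimePeakFraction = fivePrimePeakFraction,
              antisenseRate = antisenseRate, backgroundRate = backgroundRate,
              meanlog = meanlog, sdlog = sdlog)
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Default neighbor plan
#'
#' Covers all four configurations for vlincRNA-gene pairs (planted positive
#' correlation that insulators do not remove) and gene-gene pairs (weak
#' correlation, with the adjacent head-to-head pairs decoupled by an
#' insulator -- the barrier behaviour the analysis is designed to detect).
#'
#' @return the plan data.frame (see \code{\link{simulationConfig}}).
#' @export
defaultNeighborPlan <- function() {
  cfgs <- c("same_upstream", "same_downstream",
            "opposite_tail_to_tail", "opposite_head_to_head")
  rbind(
    data.frame(pair_type = "vlinc_gene", configuration = cfgs,
               distance = 500, insulator = FALSE, target_rho = 0.5, n = 5),
    data.frame(pair_type = "vlinc_gene", configuration = cfgs,
               distance = 500, insulator = TRUE, target_rho = 0.45, n = 4),
    data.frame(pair_type = "vlinc_gene", configuration = "same_downstream",
               distance = 30000, insulator = FALSE, target_rho = 0.3, n = 4),
    data.frame(pair_type = "gene_gene", configuration = cfgs,
               distance = 500, insulator = FALSE,
               target_rho = c(0.1, 0.1, 0.08, 0.3), n = 5),
    data.frame(pair_type = "gene_gene",
               configuration = "opposite_head_to_head",
               distance = 500, insulator = TRUE, target_rho = 0.03, n = 5),
    data.frame(pair_type = "gene_gene", configuration = c(
               "same_upstream", "same_downstream", "opposite_tail_to_tail"),
               distance = 500, insulator = TRUE, target_rho = 0.08, n = 3)
  )
}

# Deterministic per-stage substream seeds, all < 2^31.
deriveSeed <- function(seed, stream) {
  streams <- c(annotation = 11L, expression = 23L, tags = 37L,
               pipeline = 53L, go = 67L, mirna = 79L, regions = 97L)
  offs <- streams[[stream]]
  as.integer((as.numeric(seed) * 7919 + offs * 104729) %% 2147483629)
}

# Strand layout realizing a configuration with feature A left, B right.
.configStrands <- function(configuration) {
  switch(configuration,
    same_downstream       = c(a = "+", b = "+"),
    same_upstream         = c(a = "-", b = "-"),
    opposite_head_to_head = c(a = "-", b = "+"),
    opposite_tail_to_tail = c(a = "+", b = "-"),
    stop("unknown configuration: ", configuration))
}

#' Generate the synthetic annotation bundle
#'
#' Lays out a genome realizing every neighbor-plan entry exactly
#' (configuration, gap distance, insulator presence), places promoters at a
#' configured fraction of vlincRNA transcription start sites (with the
#' configured LTR-overlap and TF-peak fractions), scatters rRNA repeats,
#' decoy opposite-strand exons and EST 5' ends inside some vlincRNA bodies
#' to exercise the masking rules, and reserves isolated (distal) vlincRNAs
#' and filler genes, including pre-miRNA loci and three designated
#' pluripotency-factor transcripts.
#'
#' Deterministic given \code{cfg$seed}. Fails before emitting anything if
#' the requested features cannot fit on the configured chromosomes.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @return an \code{\link{AnnotationBundle}} whose \code{metadata()$sim}
#'   records the realized plan and feature roles.
#' @export
generateAnnotation <- function(cfg) {
  set.seed(deriveSeed(cfg$seed, "annotation"))
  plan <- cfg$neighborPlan
  plan <- plan[rep(seq_len(nrow(plan)), plan$n), ]
  plan$n <- NULL
  rownames(plan) <- NULL
  nPlan <- nrow(plan)
  nPlanVlinc <- sum(plan$pair_type == "vlinc_gene")
  nPlanGenes <- nPlan + sum(plan$pair_type == "gene_gene")
  if (cfg$nVlincs < nPlanVlinc + 10L)
    stop("nVlincs too small for the neighbor plan")
  if (cfg$nGenes < nPlanGenes + 20L)
    stop("nGenes too small for the neighbor plan")

  chroms <- paste0("chr", seq_len(cfg$nChrom))
  cursor <- stats::setNames(rep(1e5, cfg$nChrom), chroms)
  blockGap <- 1.2e5  # keeps unplanned features beyond the pairing horizon

  # vectorized accumulators; GRanges built once at the end
  vlR <- list(chr = character(0), start = numeric(0), width = numeric(0),
              strand = character(0))
  gnR <- vlR
  insR <- list(chr = character(0), start = numeric(0), width = numeric(0))
  addVl <- function(chr, s, w, str) {
    vlR$chr <<- c(vlR$chr, chr); vlR$start <<- c(vlR$start, s)
    vlR$width <<- c(vlR$width, w); vlR$strand <<- c(vlR$strand, str)
    paste0("vlinc", length(vlR$chr))
  }
  addGn <- function(chr, s, w, str) {
    gnR$chr <<- c(gnR$chr, chr); gnR$start <<- c(gnR$start, s)
    gnR$width <<- c(gnR$width, w); gnR$strand <<- c(gnR$strand, str)
    paste0("tx", length(gnR$chr))
  }
  pickChrom <- function(need) {
    ok <- chroms[cursor[chroms] + need < cfg$chromLength - 1e5]
    if (!length(ok)) stop("features cannot fit on the configured genome")
    ok[which.max(cfg$chromLength - cursor[ok])]
  }

  planA <- planB <- character(nPlan)
  for (i in seq_len(nPlan)) {
    st <- .configStrands(plan$configuration[i])
    lenA <- if (plan$pair_type[i] == "vlinc_gene")
      round(stats::runif(1, cfg$vlincLengthRange[1], cfg$vlincLengthRange[2]))
    else round(stats::runif(1, cfg$geneLengthRange[1], cfg$geneLengthRange[2]))
    lenB <- round(stats::runif(1, cfg$geneLengthRange[1],
                               cfg$geneLengthRange[2]))
    need <- lenA + plan$distance[i] + lenB + blockGap
    chrom <- pickChrom(need)
    s <- cursor[[chrom]]
    planA[i] <- if (plan$pair_type[i] == "vlinc_gene")
      addVl(chrom, s, lenA, st[["a"]]) else addGn(chrom, s, lenA, st[["a"]])
    bStart <- s + lenA + plan$distance[i]
    planB[i] <- addGn(chrom, bStart, lenB, st[["b"]])
    if (plan$insulator[i]) {
      d <- plan$distance[i]
      w <- max(1L, min(200L, d - 2L))
      insR$chr <- c(insR$chr, chrom)
      insR$start <- c(insR$start, s + lenA + (d - w) %/% 2L)
      insR$width <- c(insR$width, w)
    }
    cursor[[chrom]] <- bStart + lenB + blockGap
  }
  plan$a_id <- planA
  plan$b_id <- planB
  plan$pair_id <- paste0("plan", seq_len(nPlan))

  # isolated (distal) vlincRNAs
  nFree <- cfg$nVlincs - nPlanVlinc
  freeIds <- character(nFree)
  for (i in seq_len(nFree)) {
    len <- round(stats::runif(1, cfg$vlincLengthRange[1],
                              cfg$vlincLengthRange[2]))
    chrom <- pickChrom(len + blockGap)
    freeIds[i] <- addVl(chrom, cursor[[chrom]], len, sample(c("+", "-"), 1))
    cursor[[chrom]] <- cursor[[chrom]] + len + blockGap
  }

  # filler genes (miRNA targets, TF transcripts, GO universe padding)
  nFreeGenes <- cfg$nGenes - length(gnR$chr)
  for (i in seq_len(nFreeGenes)) {
    len <- round(stats::runif(1, cfg$geneLengthRange[1],
                              cfg$geneLengthRange[2]))
    chrom <- pickChrom(len + blockGap)
    addGn(chrom, cursor[[chrom]], len, sample(c("+", "-"), 1))
    cursor[[chrom]] <- cursor[[chrom]] + len + blockGap
  }

  # masking decoys inside the first isolated vlincRNAs: an rRNA repeat, a
  # short opposite-strand decoy gene, and a same-strand EST 5' end
  nDecoy <- min(10L, nFree)
  decoyHost <- freeIds[seq_len(nDecoy)]
  hostIdx <- match(decoyHost, paste0("vlinc", seq_along(vlR$chr)))
  hostMid <- vlR$start[hostIdx] + vlR$width[hostIdx] %/% 2
  rrna <- GRanges(vlR$chr[hostIdx], IRanges(hostMid, width = 500))
  est <- GRanges(vlR$chr[hostIdx], IRanges(hostMid + 20000, width = 1),
                 strand = vlR$strand[hostIdx])
  decoyStrand <- ifelse(vlR$strand[hostIdx] == "+", "-", "+")
  decoyIds <- character(nDecoy)
  for (i in seq_len(nDecoy))
    decoyIds[i] <- addGn(vlR$chr[hostIdx[i]], vlR$start[hostIdx[i]] + 2000,
                         3000, decoyStrand[i])

  vlincs <- GRanges(vlR$chr, IRanges(vlR$start, width = vlR$width),
                    strand = vlR$strand,
                    vlinc_id = paste0("vlinc", seq_along(vlR$chr)))
  genes <- GRanges(gnR$chr, IRanges(gnR$start, width = gnR$width),
                   strand = gnR$strand,
                   tx_id = paste0("tx", seq_along(gnR$chr)))
  gIds <- mcols(genes)$tx_id
  vIds <- mcols(vlincs)$vlinc_id

  # exons: 3 per gene spanning ~40% of the body (decoy genes: 2 x 600 bp)
  isDecoy <- gIds %in% decoyIds
  nExV <- ifelse(isDecoy, 2L, 3L)
  w <- gnR$width
  exw <- ifelse(isDecoy, 600, pmax(100, round(w * 0.4 / 3)))
  step <- ifelse(isDecoy, 1500, exw + (w - 3 * exw) %/% 3)
  gi <- rep(seq_along(genes), nExV)
  k <- unlist(lapply(nExV, seq_len)) - 1L
  exStarts <- gnR$start[gi] + k * step[gi]
  exAll <- GRanges(gnR$chr[gi], IRanges(exStarts, width = exw[gi]),
                   strand = gnR$strand[gi])
  exons <- GenomicRanges::split(exAll, factor(gi, levels = seq_along(genes)))
  names(exons) <- NULL

  # promoters, LTR overlap and TF peaks at vlincRNA TSSs
  nProm <- round(cfg$promoterFraction * length(vlincs))
  promVl <- sample(vIds, nProm)
  nLtr <- round(cfg$ltrFraction * nProm)
  ltrVl <- sample(promVl, nLtr)
  tfVl <- c(sample(ltrVl, round(cfg$tfFraction * length(ltrVl))),
            sample(setdiff(promVl, ltrVl),
                   round(cfg$tfFraction * (nProm - nLtr))))
  states <- c("Active", "Weak", "Poised")
  vTss <- fivePrimePos(vlincs)
  pvIdx <- match(promVl, vIds)
  promGR <- GRanges(as.character(seqnames(vlincs))[pvIdx],
                    IRanges(pmax(1, vTss[pvIdx] - 500), vTss[pvIdx] + 500),
                    state = sample(states, nProm, replace = TRUE,
                                   prob = c(.6, .25, .15)),
                    cell_line = "simCell")
  ltIdx <- match(ltrVl, vIds)
  ltrRep <- GRanges(as.character(seqnames(vlincs))[ltIdx],
                    IRanges(pmax(1, vTss[ltIdx] - 300), vTss[ltIdx] + 200))
  tfIdx <- match(tfVl, vIds)
  tfPeaks <- GRangesList(lapply(seq_len(3), function(j)
    GRanges(as.character(seqnames(vlincs))[tfIdx],
            IRanges(vTss[tfIdx] - 100 + 40 * (j - 1), width = 80))))
  names(tfPeaks) <- c("SOX2", "OCT4", "NANOG")

  # gene promoters (half the genes, needed for the gene-side TF analysis)
  promGenes <- sample(gIds, round(0.5 * length(gIds)))
  pgIdx <- match(promGenes, gIds)
  gTss <- fivePrimePos(genes)
  promG <- GRanges(as.character(seqnames(genes))[pgIdx],
                   IRanges(pmax(1, gTss[pgIdx] - 300), gTss[pgIdx] + 300),
                   state = sample(states, length(pgIdx), replace = TRUE),
                   cell_line = "simCell")
  promoters <- c(promGR, promG)

  # pre-miRNA loci in fresh isolated positions
  nMir <- cfg$mirnaPlan$n_mirnas
  mirChr <- character(nMir); mirStart <- numeric(nMir)
  for (i in seq_len(nMir)) {
    chrom <- pickChrom(80 + blockGap)
    mirChr[i] <- chrom; mirStart[i] <- cursor[[chrom]]
    cursor[[chrom]] <- cursor[[chrom]] + 80 + blockGap
  }
  mirnas <- GRanges(mirChr, IRanges(mirStart, width = 80),
                    strand = sample(c("+", "-"), nMir, replace = TRUE),
                    mirna_id = paste0("mir", seq_len(nMir)))

  # validated-target assignment from filler genes untouched by the plan
  fillerIds <- setdiff(gIds, c(plan$a_id, plan$b_id, decoyIds))
  tfGeneIds <- fillerIds[1:3]
  names(tfGeneIds) <- c("SOX2", "OCT4", "NANOG")
  targetPool <- setdiff(fillerIds, tfGeneIds)
  perMir <- cfg$mirnaPlan$targets_per_mirna
  if (length(targetPool) < nMir * perMir)
    stop("not enough filler genes for miRNA target assignment")
  tgt <- split(targetPool[seq_len(nMir * perMir)],
               rep(seq_len(nMir), each = perMir))
  names(tgt) <- mcols(mirnas)$mirna_id

  sim <- list(plan = plan,
              promoter_vlincs = promVl, ltr_vlincs = ltrVl,
              tf_vlincs = tfVl, decoy_hosts = decoyHost,
              tf_genes = tfGeneIds, mirnas = mirnas,
              mirna_targets = tgt,
              chrom_lengths = stats::setNames(rep(cfg$chromLength,
                                                  cfg$nChrom), chroms))
  insGR <- if (length(insR$chr))
    GRanges(insR$chr, IRanges(insR$start, width = insR$width)) else GRanges()
  bundle <- AnnotationBundle(genes = genes, exons = exons, vlincs = vlincs,
                             promoters = promoters, insulators = insGR,
                             ltrRepeats = ltrRep, rrnaRepeats = rrna,
                             tfPeaks = tfPeaks, est5p = est)
  metadata(bundle)$sim <- sim
  bundle
}

# Pearson latent correlation giving a target Spearman under a Gaussian
# copula: rho_s = (6/pi) asin(r/2)  =>  r = 2 sin(pi rho_s / 6).
.copulaR <- function(rhoS) 2 * sin(pi * rhoS / 6)

#' Generate latent expression with planted correlation structure
#'
#' Abundances have log-normal marginals obtained by transforming latent
#' Gaussians (a Gaussian copula), so a planted latent correlation
#' translates into an exact expected rank correlation -- rank statistics
#' are invariant to the monotone marginal transform. Each neighbor-plan
#' pair, each miRNA-target pair (negative), and each LTR/TF-bound vlincRNA
#' versus the pluripotency-factor program along the differentiation time
#' course receives its configured target Spearman. LTR-vlincRNA rows are
#' multiplied by \code{cancerEffect} in cancer and stem columns, boosting
#' their expression maxima there.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @param bundle the matching \code{\link{generateAnnotation}} output.
#' @return list of class \code{LatentExpression}: \code{abundance} (feature
#'   x sample matrix), \code{samples} (data.frame: sample_id, class,
#'   timecourse_id, time_index), \code{provenance} (the realized plan with
#'   planted rho).
#' @export
generateExpression <- function(cfg, bundle) {
  set.seed(deriveSeed(cfg$seed, "expression"))
  sim <- metadata(bundle)$sim
  gIds <- mcols(geneBodies(bundle))$tx_id
  vIds <- mcols(vlincRanges(bundle))$vlinc_id
  mIds <- mcols(sim$mirnas)$mirna_id
  feats <- c(gIds, vIds, mIds)

  ns <- cfg$nSamples
  classes <- rep(names(ns), ns)
  nMain <- length(classes)
  nTc <- cfg$timecourse$n_points
  samples <- data.frame(
    sample_id = c(sprintf("s%03d", seq_len(nMain)),
                  sprintf("tc%02d", seq_len(nTc))),
    class = c(classes, rep("stem", nTc)),
    timecourse_id = c(rep(NA_character_, nMain), rep("tc1", nTc)),
    time_index = c(rep(NA_integer_, nMain), seq_len(nTc)),
    stringsAsFactors = FALSE)
  nTot <- nMain + nTc

  z <- matrix(stats::rnorm(length(feats) * nTot), length(feats), nTot,
              dimnames = list(feats, samples$sample_id))

  plantPair <- function(aId, bId, rhoS, cols) {
    r <- .copulaR(rhoS)
    if (abs(r) > 1) stop("planted correlation block for pair ", aId, "-",
                         bId, " is not attainable")
    z[bId, cols] <<- r * z[aId, cols] +
      sqrt(1 - r^2) * stats::rnorm(length(cols))
  }
  mainCols <- seq_len(nMain)
  for (i in seq_len(nrow(sim$plan)))
    plantPair(sim$plan$a_id[i], sim$plan$b_id[i],
              sim$plan$target_rho[i], mainCols)
  for (m in names(sim$mirna_targets))
    for (t in sim$mirna_targets[[m]])
      plantPair(m, t, cfg$mirnaPlan$target_rho, mainCols)

  # differentiation time course: a strictly decreasing pluripotency
  # program drives the three TFs exactly and the LTR/TF-bound vlincRNAs
  # at the configured coupling
  tcCols <- nMain + seq_len(nTc)
  prog <- stats::qnorm((nTc + 1 - seq_len(nTc)) / (nTc + 1))
  for (f in sim$tf_genes) z[f, tcCols] <- prog
  rTf <- .copulaR(cfg$timecourse$tf_coupling_rho)
  tfLtr <- intersect(sim$tf_vlincs, sim$ltr_vlincs)
  for (v in tfLtr)
    z[v, tcCols] <- rTf * prog + sqrt(1 - rTf^2) * stats::rnorm(nTc)

  x <- stats::qlnorm(stats::pnorm(z), meanlog = cfg$meanlog,
                     sdlog = cfg$sdlog)
  boostCols <- which(samples$class %in% c("cancer", "stem"))
  x[sim$ltr_vlincs, boostCols] <- x[sim$ltr_vlincs, boostCols] *
    cfg$cancerEffect

  out <- list(abundance = x, samples = samples, provenance = sim$plan)
  class(out) <- "LatentExpression"
  out
}

# Sample tag offsets (0-based, from the 5' end of the unmasked transcript
# space of total length L): a 5' peak within the first 500 bp plus a
# linearly decreasing body component.
.sampleOffsets <- function(n, L, peakFraction) {
  if (n == 0L || L <= 0) return(integer(0))
  nPeak <- stats::rbinom(1, n, peakFraction)
  peak <- if (nPeak) sample.int(min(500L, L), nPeak, replace = TRUE) - 1L
          else integer(0)
  nBody <- n - nPeak
  body <- if (nBody) pmin(L - 1L, floor(L * (1 - sqrt(stats::runif(nBody)))))
          else integer(0)
  c(peak, body)
}

#' Generate per-sample tag sets from latent expression
#'
#' Per feature and sample the tag count is Poisson with mean proportional
#' to the latent abundance, scaled so a sample's expected feature-tag total
#' is \code{tagDepth * (1 - backgroundRate)}. Tag 5' positions follow a
#' mixture: a configurable fraction lands within the first 500 bp of the
#' feature's unmasked 5' end and the remainder follows a linearly
#' decreasing density along the unmasked body, emulating 5'-enriched but
#' body-covering capped-tag coverage. For vlincRNAs the peak fraction is
#' drawn per feature (uniform on 0.05-0.95), emulating imprecise,
#' repeat-buried 5' ends whose flank signal is an unreliable abundance
#' readout. Tags are strand-matched to the
#' feature up to a small antisense noise rate; uniform background tags are
#' added, and the informative total excludes tags falling in rRNA repeats.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @param bundle the annotation bundle.
#' @param latent \code{\link{generateExpression}} output.
#' @return named list of \code{\link{TagSet}} objects, one per sample.
#' @export
generateTags <- function(cfg, bundle, latent) {
  set.seed(deriveSeed(cfg$seed, "tags"))
  sim <- metadata(bundle)$sim
  genes <- geneBodies(bundle)
  vlincs <- vlincRanges(bundle)
  mirnas <- sim$mirnas

  # per-feature sense-strand emission space as plain start/end vectors
  masks <- c(granges(unlist(geneExons(bundle))), granges(rrnaRepeats(bundle)))
  exAll <- unlist(geneExons(bundle))
  exFeat <- rep(seq_along(genes), lengths(geneExons(bundle)))
  featIds <- c(mcols(genes)$tx_id, mcols(vlincs)$vlinc_id,
               mcols(mirnas)$mirna_id)
  nG <- length(genes); nV <- length(vlincs); nM <- length(mirnas)
  featStrand <- c(as.character(GenomicRanges::strand(genes)),
                  as.character(GenomicRanges::strand(vlincs)),
                  as.character(GenomicRanges::strand(mirnas)))
  featChrom <- c(as.character(seqnames(genes)),
                 as.character(seqnames(vlincs)),
                 as.character(seqnames(mirnas)))
  featFrag <- vector("list", nG + nV + nM)
  exS <- GenomicRanges::start(exAll); exE <- GenomicRanges::end(exAll)
  byGene <- split(seq_along(exAll), exFeat)
  for (i in seq_len(nG))
    featFrag[[i]] <- cbind(exS[byGene[[i]]], exE[byGene[[i]]])
  for (i in seq_len(nV)) {
    fr <- subtractMasks(vlincs[i], masks, "any")
    featFrag[[nG + i]] <- cbind(GenomicRanges::start(fr),
                                GenomicRanges::end(fr))
  }
  for (i in seq_len(nM))
    featFrag[[nG + nV + i]] <-
      cbind(max(1L, GenomicRanges::start(mirnas)[i] - 1000L),
            GenomicRanges::end(mirnas)[i] + 1000L)
  featLen <- vapply(featFrag, function(f)
    sum(f[, 2] - f[, 1] + 1), 0)
  # vlincRNA 5' ends are imprecise and often repeat-buried, so their
  # peak prominence varies widely feature to feature; genes keep the
  # configured fraction. This is what makes flank-window counting a
  # poorly calibrated estimator for vlincRNAs.
  featPeak <- c(rep(cfg$fivePrimePeakFraction, nG),
                stats::runif(nV, 0.05, 0.95),
                rep(cfg$fivePrimePeakFraction, nM))
  names(featFrag) <- names(featLen) <- names(featPeak) <- featIds

  x <- latent$abundance
  feats <- rownames(x)
  fragOf <- featFrag[feats]; lenOf <- featLen[feats]
  peakOf <- featPeak[feats]
  strandOf <- stats::setNames(featStrand, featIds)[feats]
  chromOf <- stats::setNames(featChrom, featIds)[feats]
  chromLen <- sim$chrom_lengths
  rr <- rrnaRepeats(bundle)
  out <- vector("list", ncol(x))
  names(out) <- colnames(x)
  for (s in seq_len(ncol(x))) {
    ab <- x[, s]
    lam <- ab / sum(ab) * cfg$tagDepth * (1 - cfg$backgroundRate)
    cnt <- stats::rpois(length(lam), lam)
    posL <- list(); strL <- list(); chrL <- list()
    for (f in which(cnt > 0L)) {
      off <- .sampleOffsets(cnt[f], lenOf[[f]], peakOf[[f]])
      if (!length(off)) next
      gpos <- .offsetsToGenomeMat(off, fragOf[[f]], strandOf[[f]])
      str <- rep(strandOf[[f]], length(gpos))
      flip <- stats::runif(length(gpos)) < cfg$antisenseRate
      str[flip] <- ifelse(str[flip] == "+", "-", "+")
      posL[[length(posL) + 1L]] <- gpos
      strL[[length(strL) + 1L]] <- str
      chrL[[length(chrL) + 1L]] <- rep(chromOf[[f]], length(gpos))
    }
    nBg <- stats::rpois(1, cfg$tagDepth * cfg$backgroundRate)
    bgChrom <- sample(names(chromLen), nBg, replace = TRUE)
    posL[[length(posL) + 1L]] <-
      floor(stats::runif(nBg, 1, chromLen[bgChrom]))
    strL[[length(strL) + 1L]] <- sample(c("+", "-"), nBg, replace = TRUE)
    chrL[[length(chrL) + 1L]] <- bgChrom
    tags <- GRanges(unlist(chrL), IRanges(unlist(posL), width = 1),
                    strand = unlist(strL))
    inRrna <- GenomicRanges::countOverlaps(tags, rr,
                                           ignore.strand = TRUE) > 0
    informative <- length(tags) - sum(inRrna)
    out[[s]] <- TagSet(colnames(x)[s], tags, informative)
  }
  out
}

# matrix-form variant of the offsets-to-genome walk (frags: start/end cols)
.offsetsToGenomeMat <- function(offsets, frags, strand) {
  w <- frags[, 2] - frags[, 1] + 1
  if (strand == "-") frags <- frags[rev(seq_len(nrow(frags))), , drop = FALSE]
  if (strand == "-") w <- rev(w)
  cum <- cumsum(w)
  idx <- findInterval(offsets, c(0, cum[-length(cum)]))
  within <- offsets - c(0, cum)[idx]
  if (strand == "-") frags[idx, 2] - within else frags[idx, 1] + within
}
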