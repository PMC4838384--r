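#' Run the complete analysis pipeline on a synthetic fixture world
#'
#' Orchestrates the stages end-to-end: simulate (annotation, latent
#' expression, tag sets; tracks written as BED/TSV), quantify (internal
#' counting + RPKM), annotate (promoters/LTR/TF/distal), build genes
#' (standalone designation + strand-specific merge), neighbor correlation
#' tables, class metrics (RMECN, permutation test, mass fractions, top-N
#' enrichment, time-course trend), regulators (miRNA targets, TF
#' correlations, flank enrichment) and the two-level GO analysis. All
#' randomness flows from \code{cfg$seed} through named per-stage
#' substreams, so a config plus seed reproduces identical outputs.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @param outDir output directory for TSV/BED artifacts (created).
#' @param nPerm permutations for the RMECN label test (default 200; the
#'   desk-scale default keeps the full run under a couple of minutes).
#' @param goVlincs number of vlincRNA genes profiled in the GO stage
#'   (default 40).
#' @return invisible list: \code{manifest} plus every stage result
#'   (\code{bundle}, \code{expr}, \code{annotation}, \code{standalone},
#'   \code{vlincGenes}, \code{tables}, \code{classMetrics},
#'   \code{regulators}, \code{go}).
#' @export
runPipeline <- function(cfg = simulationConfig(), outDir = tempfile("vlincrun"),
                        nPerm = 200L, goVlincs = 40L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_fingerprint = configFingerprint(cfg),
                   seed = cfg$seed, stages = list())
  note <- function(stage, outputs, n) {
    manifest$stages[[stage]] <<- list(outputs = outputs, rows = n)
  }

  # -- simulate ---------------------------------------------------------
  bundle <- generateAnnotation(cfg)
  latent <- generateExpression(cfg, bundle)
  tagsets <- generateTags(cfg, bundle, latent)
  writeAnnotationBundle(bundle, file.path(outDir, "tracks"))
  utils::write.table(latent$samples, file.path(outDir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("simulate", c("tracks/", "samples.tsv"), length(tagsets))

  # -- quantify ---------------------------------------------------------
  sim <- metadata(bundle)$sim
  expr <- quantifyExpression(bundle, tagsets, mode = "internal",
                             mirnas = sim$mirnas,
                             colData = latent$samples)
  exprPath <- file.path(outDir, "expression.tsv")
  utils::write.table(round(rpkmValues(expr), 6), exprPath, sep = "\t",
                     quote = FALSE, col.names = NA)
  note("quantify", "expression.tsv", nrow(expr))

  # -- annotate ---------------------------------------------------------
  annotation <- annotateVlincs(bundle)
  annPath <- file.path(outDir, "vlinc_annotation.tsv")
  annDf <- as.data.frame(annotation[, setdiff(colnames(annotation),
                                              "promoters")])
  utils::write.table(annDf, annPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  note("annotate", "vlinc_annotation.tsv", nrow(annotation))

  # -- build genes ------------------------------------------------------
  standalone <- designateStandalone(vlincRanges(bundle), geneBodies(bundle),
                                    insulatorElements(bundle))
  vlincGenes <- buildGenes(vlincRanges(bundle)[standalone$standalone])
  utils::write.table(standalone, file.path(outDir, "standalone.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gg <- granges(vlincGenes); mcols(gg)$name <- mcols(vlincGenes)$gene_id
  writeBed(gg, file.path(outDir, "vlinc_genes.bed"))
  note("build_genes", c("standalone.tsv", "vlinc_genes.bed"),
       length(vlincGenes))

  # -- neighbors --------------------------------------------------------
  mainCols <- is.na(latent$samples$timecourse_id)
  exprMain <- rpkmValues(expr)[, mainCols, drop = FALSE]
  vg <- neighborPairs(vlincRanges(bundle), geneBodies(bundle),
                      insulatorElements(bundle))
  ggp <- neighborPairs(geneBodies(bundle), geneBodies(bundle),
                       insulatorElements(bundle))
  tabV <- correlationTable(exprMain, vg, "vlinc_gene")
  tabG <- correlationTable(exprMain, ggp, "gene_gene")
  tables <- rbind(tabV, tabG)
  utils::write.table(tables, file.path(outDir, "correlation_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("neighbors", "correlation_table.tsv", nrow(tables))

  # -- class metrics ----------------------------------------------------
  samplesMain <- latent$samples[mainCols, ]
  rm_ <- rmecn(exprMain, samplesMain, annotation)
  perm <- labelPermutationTest(exprMain, samplesMain, annotation,
                               nPerm = nPerm,
                               seed = deriveSeed(cfg$seed, "pipeline"))
  maxloc <- maxLocationCounts(exprMain, samplesMain, annotation)
  distalLtr <- with(as.data.frame(annotation),
                    vlinc_id[distal & category == "LTR"])
  distalNon <- with(as.data.frame(annotation),
                    vlinc_id[distal & category == "nonLTR"])
  vl <- vlincRanges(bundle)
  sets <- list(distal_LTR = vl[mcols(vl)$vlinc_id %in% distalLtr],
               distal_nonLTR = vl[mcols(vl)$vlinc_id %in% distalNon])
  fr <- massFractions(tagsets, sets, bundle)
  frLtrMain <- with(fr[fr$set == "distal_LTR" &
                         fr$sample_id %in% samplesMain$sample_id, ],
                    stats::setNames(frac_informative, sample_id))
  topn <- topNClassEnrichment(frLtrMain, samplesMain,
                              n = min(20L, nrow(samplesMain)), "cancer")
  clsTests <- classFractionTests(frLtrMain, samplesMain)
  tcRows <- !mainCols
  frTc <- fr[fr$set == "distal_LTR" &
               fr$sample_id %in% latent$samples$sample_id[tcRows], ]
  frTc <- frTc[match(latent$samples$sample_id[tcRows], frTc$sample_id), ]
  trend <- timecourseTrend(frTc$frac_informative,
                           latent$samples$time_index[tcRows])
  utils::write.table(rm_$perVlinc, file.path(outDir, "rmecn.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fr, file.path(outDir, "mass_fractions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  classMetrics <- list(rmecn = rm_, permutation = perm, maxLocation = maxloc,
                       fractions = fr, topN = topn, classTests = clsTests,
                       trend = trend)
  note("class_metrics", c("rmecn.tsv", "mass_fractions.tsv"),
       nrow(rm_$perVlinc))

  # -- regulators -------------------------------------------------------
  mir <- mirnaTargetProfile(exprMain, sim$mirna_targets,
                            mcols(geneBodies(bundle))$tx_id,
                            seed = deriveSeed(cfg$seed, "mirna"))
  exprTc <- rpkmValues(expr)[, !mainCols, drop = FALSE]
  tfc <- tfGroupCorrelations(exprTc, sim$tf_genes, annotation)
  flank <- flankPeakEnrichment(vl, unlist(tfPeaks(bundle)),
                               sim$chrom_lengths, nPerm = 200L,
                               seed = deriveSeed(cfg$seed, "regions"))
  regulators <- list(mirna = mir, tf = tfc, flank = flank)
  utils::write.table(mir$summary, file.path(outDir, "mirna_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("regulators", "mirna_profile.tsv",
       if (is.null(mir$summary)) 0L else nrow(mir$summary))

  # -- GO ---------------------------------------------------------------
  onto <- syntheticOntology(seed = deriveSeed(cfg$seed, "go"))
  geneIds <- mcols(geneBodies(bundle))$tx_id
  geneGo <- makeGeneGoMap(geneIds, onto,
                          seed = deriveSeed(cfg$seed, "go"))
  vlincIds <- mcols(vl)$vlinc_id[seq_len(min(goVlincs, length(vl)))]
  profiles <- vlincGoProfiles(exprMain, vlincIds, geneGo)
  ltrIds <- intersect(vlincIds, with(as.data.frame(annotation),
                                     vlinc_id[category == "LTR"]))
  goRes <- if (length(ltrIds))
    subsetEnrichment(profiles, ltrIds, vlincIds, "pos")
  else NULL
  if (!is.null(goRes))
    utils::write.table(goRes, file.path(outDir, "go_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  note("go", "go_enrichment.tsv",
       if (is.null(goRes)) 0L else nrow(goRes))

  res <- list(manifest = manifest, bundle = bundle, latent = latent,
              tagsets = tagsets, expr = expr, annotation = annotation,
              standalone = standalone, vlincGenes = vlincGenes,
              tables = tables, classMetrics = classMetrics,
              regulators = regulators,
              go = list(ontology = onto, profiles = profiles,
                        enrichment = goRes))
  reportPath <- file.path(outDir, "report.txt")
  writeLines(pipelineReport(res), reportPath)
  res$manifest$stages$report <- list(outputs = "report.txt", rows = NA)
  invisible(res)
}

# cheap deterministic fingerprint of a config (no external digest dep)
configFingerprint <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

#' Render a pipeline run as a readable text report
#'
#' @param res a \code{\link{runPipeline}} result list.
#' @return character vector of report lines.
#' @export
pipelineReport <- function(res) {
  ln <- c("vlincCAGE pipeline report",
          paste0("seed: ", res$manifest$seed,
                 "  config: ", res$manifest$config_fingerprint), "")
  ln <- c(ln, "== standalone designation ==")
  tb <- table(res$standalone$reason)
  ln <- c(ln, paste0("  ", names(tb), ": ", as.integer(tb)),
          paste0("  vlincRNA genes after merge: ",
                 length(res$vlincGenes)), "")
  ln <- c(ln, "== neighbor correlation (median rho; all-stratum cells) ==")
  tab <- res$tables
  sel <- tab$stratum == "all" & !is.na(tab$median_rho)
  if (any(sel)) {
    t2 <- tab[sel, c("pair_type", "configuration", "bin", "median_rho",
                     "n_pairs")]
    ln <- c(ln, utils::capture.output(print(t2, row.names = FALSE)))
  } else ln <- c(ln, "  no data")
  cm <- res$classMetrics
  ln <- c(ln, "", "== class metrics ==",
          sprintf("  median RMECN LTR %.3f nonLTR %.3f ratio %.3f",
                  cm$rmecn$medians["LTR"], cm$rmecn$medians["nonLTR"],
                  cm$rmecn$ratio),
          sprintf("  label permutation p = %.4g", cm$permutation$p),
          sprintf("  max-in-cancer Fisher p = %.3g", cm$maxLocation$p),
          sprintf("  top-N cancer enrichment p = %.3g (k = %d, expected %.1f)",
                  cm$topN$p, cm$topN$k, cm$topN$expected),
          sprintf("  time-course trend: %s (p = %s)", cm$trend$direction,
                  format(cm$trend$p)))
  mir <- res$regulators$mirna
  ln <- c(ln, "", "== regulators ==",
          if (!is.null(mir$summary))
            sprintf("  miRNA: median real rho %.3f, random %.3f, KS p %.3g",
                    stats::median(mir$summary$median_rho_real),
                    stats::median(mir$summary$median_rho_random), mir$ks_p)
          else "  miRNA: no data",
          sprintf("  TF flank enrichment p = %.4g", res$regulators$flank$p))
  go <- res$go$enrichment
  ln <- c(ln, "", "== GO enrichment (top rows) ==")
  if (!is.null(go) && nrow(go))
    ln <- c(ln, utils::capture.output(
      print(utils::head(go, 5), row.names = FALSE)))
  else ln <- c(ln, "  no data")
  ln
}
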