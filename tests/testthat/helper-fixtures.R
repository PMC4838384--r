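# Shared fixture worlds, generated once per test session.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- force(expr)
  .fixtureCache[[key]]
}

# default synthetic world incl. tags and full pipeline outputs
sharedPipeline <- function() {
  cached("pipeline", {
    suppressMessages(runPipeline(simulationConfig(seed = 101L),
                                 outDir = file.path(tempdir(), "vc_run")))
  })
}

# compendium-scale expression-only fixture for planted-effect recovery:
# paper-sized sample classes, every vlincRNA promoter-assigned, half LTR
rmecnFixtureConfig <- function(seed, nVlincs = 600L) {
  plan <- defaultNeighborPlan()
  plan$n <- 1L
  simulationConfig(
    seed = seed, nVlincs = nVlincs, nGenes = 80L,
    nChrom = 10L, chromLength = 1.4e7, neighborPlan = plan,
    mirnaPlan = list(n_mirnas = 3L, targets_per_mirna = 5L,
                     target_rho = -0.4),
    promoterFraction = 1, ltrFraction = 0.5, tfFraction = 0.5,
    nSamples = c(normal = 399L, cancer = 332L, stem = 92L,
                 immortalized = 10L))
}

rmecnFixture <- function() {
  cached("rmecn", {
    cfg <- rmecnFixtureConfig(202L)
    bundle <- suppressMessages(generateAnnotation(cfg))
    latent <- generateExpression(cfg, bundle)
    ann <- suppressMessages(annotateVlincs(bundle))
    main <- is.na(latent$samples$timecourse_id)
    list(cfg = cfg, bundle = bundle, latent = latent, annotation = ann,
         expr = latent$abundance[, main], samples = latent$samples[main, ])
  })
}

# tiny world for cheap structural tests
tinyConfig <- function(seed = 5L) {
  plan <- defaultNeighborPlan()
  plan$n <- 1L
  simulationConfig(seed = seed, nVlincs = 30L, nGenes = 60L,
                   nChrom = 3L, chromLength = 1.2e7, neighborPlan = plan,
                   mirnaPlan = list(n_mirnas = 3L, targets_per_mirna = 5L,
                                    target_rho = -0.4),
                   nSamples = c(normal = 12L, cancer = 10L, stem = 3L,
                                immortalized = 1L),
                   timecourse = list(n_points = 6L, tf_coupling_rho = 0.8),
                   tagDepth = 8e3)
}

tinyWorld <- function() {
  cached("tiny", {
    cfg <- tinyConfig()
    bundle <- suppressMessages(generateAnnotation(cfg))
    latent <- generateExpression(cfg, bundle)
    tagsets <- generateTags(cfg, bundle, latent)
    list(cfg = cfg, bundle = bundle, latent = latent, tagsets = tagsets)
  })
}
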