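test_that("the synthetic ontology is a rooted DAG with closed annotations", {
  onto <- syntheticOntology(seed = 3L)
  expect_true(all(onto$terms %in% names(onto$parents)))
  expect_true(is.na(onto$parents[[onto$root]]))
  # closure: every term implies its ancestors, root excluded
  gg <- makeGeneGoMap(paste0("g", 1:50), onto, seed = 3L)
  for (g in names(gg)) {
    for (t in gg[[g]]) {
      p <- onto$parents[[t]]
      if (!is.na(p) && p != onto$root) expect_true(p %in% gg[[g]])
    }
    expect_false(onto$root %in% gg[[g]])
  }
  # count monotone up the DAG: ancestors annotate at least as many genes
  t2g <- vlincCAGE:::termToGenes(gg, names(gg))
  for (t in names(t2g)) {
    p <- onto$parents[[t]]
    if (!is.na(p) && p != onto$root)
      expect_gte(length(t2g[[p]]), length(t2g[[t]]))
  }
})

test_that("correlated gene sets respect the inclusive threshold", {
  set.seed(91)
  m <- matrix(rnorm(5 * 100), 5, 100,
              dimnames = list(c("v", paste0("g", 1:4)), NULL))
  m["g1", ] <- m["v", ]                     # rho 1
  m["g2", ] <- -m["v", ]                    # rho -1
  m["g3", ] <- 3                            # constant: dropped
  cs <- correlatedGeneSets(m, "v", paste0("g", 1:4))
  expect_true("g1" %in% cs$pos)
  expect_true("g2" %in% cs$neg)
  expect_false("g3" %in% c(cs$pos, cs$neg))
  # an impossible threshold empties both sets
  cs2 <- correlatedGeneSets(m, "v", paste0("g", 1:4), threshold = 1.01)
  expect_equal(length(cs2$pos) + length(cs2$neg), 0L)
  # boundary: rho exactly at the threshold is included
  ranks <- 1:20
  x <- rnorm(20)
  y <- x  # rho 1 >= any threshold
  mm <- rbind(v = x, g1 = y)
  cs3 <- correlatedGeneSets(mm, "v", "g1", threshold = 1)
  expect_equal(cs3$pos, "g1")
})

test_that("first-level term recording follows the unadjusted p threshold", {
  onto <- syntheticOntology(seed = 5L)
  universe <- paste0("g", 1:200)
  gg <- makeGeneGoMap(universe, onto, seed = 5L)
  # gene set equal to exactly one small term's annotation: term kept
  t2g <- vlincCAGE:::termToGenes(gg, universe)
  sizes <- lengths(t2g)
  small <- names(sizes)[sizes >= 3 & sizes <= 15][1]
  keep <- perVlincGoTerms(t2g[[small]], gg, universe)
  expect_true(small %in% keep)
  # universe as the gene set: nothing can be enriched
  expect_equal(length(perVlincGoTerms(universe, gg, universe)), 0L)
  expect_equal(length(perVlincGoTerms(character(0), gg, universe)), 0L)
})

test_that("null calibration: ~5% of independent terms pass p < 0.05", {
  # one gene pool, disjoint single-level terms of equal size, random sets
  set.seed(92)
  universe <- paste0("g", 1:1000)
  onto <- list(parents = c(stats::setNames(NA_character_, "ROOT"),
                           stats::setNames(rep("ROOT", 20),
                                           paste0("T", 1:20))),
               root = "ROOT", terms = paste0("T", 1:20))
  gg <- lapply(universe, function(g) sample(onto$terms, 4))
  names(gg) <- universe
  hits <- 0L; total <- 0L
  for (r in 1:60) {
    gs <- sample(universe, 100)
    kept <- perVlincGoTerms(gs, gg, universe)
    hits <- hits + length(kept)
    total <- total + 20L
  }
  rate <- hits / total
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.08)
})

test_that("subset enrichment ranks a planted term first with small FDR", {
  set.seed(93)
  bg <- paste0("vg", 1:150)
  sub <- bg[1:50]
  profiles <- lapply(bg, function(v) {
    terms <- paste0("T", sample(2:30, 3))
    list(pos = terms, neg = character(0))
  })
  names(profiles) <- bg
  # plant T1 on every subset member and ~10% of the rest
  for (v in sub) profiles[[v]]$pos <- c("T1", profiles[[v]]$pos)
  for (v in sample(setdiff(bg, sub), 10))
    profiles[[v]]$pos <- c("T1", profiles[[v]]$pos)
  res <- subsetEnrichment(profiles, sub, bg, "pos")
  expect_equal(res$term[1], "T1")
  expect_lt(res$p_adj[1], 0.01)
  expect_equal(res$Count[1], 50)
  expect_equal(res$Size[1], 60)
  expect_equal(res$ExpCount[1], 50 * 60 / 150)
  # subset == background: every ExpCount equals Count and p = 1
  resAll <- subsetEnrichment(profiles, bg, bg, "pos")
  expect_true(all(resAll$ExpCount == resAll$Count))
  expect_true(all(resAll$p_raw == 1))
  # empty subset and containment violations
  expect_equal(nrow(subsetEnrichment(profiles, character(0), bg, "pos")), 0L)
  expect_error(subsetEnrichment(profiles, "nope", bg, "pos"), "contained")
  # cross-check one row against a 2x2 Fisher formulation
  r5 <- res[res$term == res$term[5], ]
  a <- r5$Count; K <- r5$Size
  expect_equal(r5$p_raw,
               fisherOneSided(a, 50 - a, K - a, 150 - 50 - (K - a)),
               tolerance = 1e-12)
})

test_that("interval overlap enrichment reproduces the corrected binomial", {
  # the plug-in computation with externally supplied intergenic expectation
  genome <- 1e7
  intergenic <- rg("chr1", 1, 6e6)
  setA <- rg("chr1", seq(1e4, 5.9e6, length.out = 100),
             seq(1e4, 5.9e6, length.out = 100) + 9999)
  setB <- rg("chr1", seq(2e4, 5e6, length.out = 10),
             seq(2e4, 5e6, length.out = 10) + 5000)
  res <- intervalOverlapEnrichment(setA, setB, genome, intergenic,
                                   expectedIntergenic = 2.5)
  obs <- sum(countOverlaps(setA, setB) > 0)
  expect_equal(res$observed, obs)
  expect_equal(res$binomial_p,
               binomialUpperTail(100, obs, (2.5 + res$genic_overlaps) / 100))
  # empty B: nothing overlaps, p = 1
  res0 <- intervalOverlapEnrichment(setA, GRanges(), genome, intergenic,
                                    expectedIntergenic = 0)
  expect_equal(res0$observed, 0L)
  expect_equal(res0$binomial_p, 1)
  expect_error(intervalOverlapEnrichment(rg("chr1", 1, 5e6), setB, genome,
                                         rg("chr1", 1, 1e6)), "intergenic")
})

test_that("the internal intergenic expectation matches Monte-Carlo placement", {
  # the closed-form expectation is exact for a contiguous B footprint
  set.seed(94)
  intergenic <- rg("chr1", 1, 2e6)
  setB <- rg("chr1", 9e5, 9.8e5)
  aS <- sample(1:1.9e6, 30)
  setA <- rg("chr1", aS, aS + 9999)
  res <- intervalOverlapEnrichment(setA, setB, 4e6, intergenic)
  # Monte-Carlo: drop each A interval uniformly into intergenic space
  interLen <- 2e6
  draws <- replicate(4000, {
    s <- sample.int(interLen - 10000, length(setA), replace = TRUE)
    sum(countOverlaps(GRanges("chr1", IRanges(s, width = width(setA))),
                      setB) > 0)
  })
  expect_lt(abs(res$expected_intergenic - mean(draws)) /
              max(mean(draws), 1), 0.1)
})
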