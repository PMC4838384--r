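mkSamples <- function(classes) data.frame(
  sample_id = paste0("s", seq_along(classes)), class = classes,
  stringsAsFactors = FALSE)

mkAnn <- function(ids, cats) S4Vectors::DataFrame(vlinc_id = ids,
                                                  category = cats)

test_that("RMECN instantiates the max-ratio definition", {
  samples <- mkSamples(c("cancer", "cancer", "normal", "normal", "stem"))
  m <- matrix(c(20, 5, 10, 3, 99,   # v1: cancer max 20, normal max 10
                4, 4, 4, 4, 4),     # v2: constant
              2, 5, byrow = TRUE,
              dimnames = list(c("v1", "v2"), samples$sample_id))
  ann <- mkAnn(c("v1", "v2"), c("LTR", "nonLTR"))
  res <- rmecn(m, samples, ann)
  expect_equal(res$perVlinc$rmecn[1], 2)
  expect_equal(res$perVlinc$rmecn[2], 1)   # stem column never enters
  # scale invariance
  res2 <- rmecn(m * 7, samples, ann)
  expect_equal(res2$perVlinc$rmecn, res$perVlinc$rmecn)
  # undefined ratios are excluded and counted
  m2 <- m; m2["v1", c("s3", "s4")] <- 0
  res3 <- rmecn(m2, samples, ann)
  expect_equal(res3$n_undefined, 1)
  expect_true(is.na(res3$perVlinc$rmecn[1]))
  expect_error(rmecn(m, mkSamples(rep("cancer", 5)), ann), "normal")
})

test_that("max-location counting recovers planted peaks and ties deterministically", {
  samples <- mkSamples(c("cancer", "normal", "normal", "stem"))
  m <- matrix(c(9, 1, 1, 1,
                1, 9, 1, 1,
                1, 1, 1, 9), 3, 4, byrow = TRUE,
              dimnames = list(c("v1", "v2", "v3"), samples$sample_id))
  ann <- mkAnn(c("v1", "v2", "v3"), c("LTR", "nonLTR", "LTR"))
  res <- maxLocationCounts(m, samples, ann)
  expect_equal(res$perVlinc$peak_class, c("cancer", "normal", "stem"))
  expect_equal(res$table["LTR", "max_in_cancer"], 1)
  res2 <- maxLocationCounts(m, samples, ann, excludeStemImmortalized = TRUE)
  expect_equal(nrow(res2$perVlinc), 2)
  # all-constant matrix warns and resolves ties to the first sample
  mc <- matrix(1, 2, 4, dimnames = list(c("v1", "v2"), samples$sample_id))
  expect_warning(res3 <- maxLocationCounts(mc, samples,
                                           mkAnn(c("v1", "v2"),
                                                 c("LTR", "nonLTR"))),
                 "tie")
  expect_equal(unique(res3$perVlinc$peak_class), "cancer")
  # random recount oracle
  set.seed(71)
  for (rep in 1:40) {
    n <- 12
    mm <- matrix(runif(n * 8), n, 8,
                 dimnames = list(paste0("v", 1:n), paste0("s", 1:8)))
    cl <- sample(c("cancer", "normal"), 8, replace = TRUE)
    sm <- mkSamples(cl)
    annR <- mkAnn(paste0("v", 1:n),
                  sample(c("LTR", "nonLTR"), n, replace = TRUE))
    res <- maxLocationCounts(mm, sm, annR)
    for (i in 1:n) {
      want <- cl[which.max(mm[i, ])]
      expect_equal(res$perVlinc$peak_class[i], want)
    }
    expect_equal(sum(res$table), n)
  }
})

test_that("label permutation reports the add-one p for a strong planted effect", {
  fx <- rmecnFixture()
  res <- labelPermutationTest(fx$expr, fx$samples, fx$annotation,
                              nPerm = 300L, seed = 9L)
  expect_equal(res$p, 1 / 301)
  expect_gt(res$observed, max(res$nullDraws))
  expect_warning(labelPermutationTest(fx$expr, fx$samples, fx$annotation,
                                      nPerm = 10L, seed = 1L), "unreliable")
})

test_that("mass fractions count masked-body tags under both normalizations", {
  w <- tinyWorld()
  ann <- suppressMessages(annotateVlincs(w$bundle))
  vl <- vlincRanges(w$bundle)
  df <- as.data.frame(ann)
  sets <- list(
    distal_LTR = vl[mcols(vl)$vlinc_id %in%
                      df$vlinc_id[df$distal & df$category == "LTR"]],
    distal_nonLTR = vl[mcols(vl)$vlinc_id %in%
                         df$vlinc_id[df$distal & df$category == "nonLTR"]])
  fr <- massFractions(w$tagsets[1:4], sets, w$bundle)
  expect_true(all(fr$frac_informative >= 0 & fr$frac_informative <= 1))
  expect_true(all(fr$frac_vlinc_mass >= 0 & fr$frac_vlinc_mass <= 1))
  # mutually exclusive sets: fractions sum to at most 1 per sample
  agg <- tapply(fr$frac_vlinc_mass, fr$sample_id, sum)
  expect_true(all(agg <= 1 + 1e-12))
  # counting oracle for one sample/set
  masks <- c(granges(unlist(geneExons(w$bundle))),
             granges(rrnaRepeats(w$bundle)))
  frag <- subtractMasks(sets$distal_LTR, masks)
  # restore per-interval strand lost in masking for oracle counting
  got <- fr[fr$sample_id == names(w$tagsets)[1] & fr$set == "distal_LTR", ]
  expect_equal(got$tags_in_set, countTags(w$tagsets[[1]], frag))
  # empty set yields zero everywhere
  fr0 <- massFractions(w$tagsets[1], list(none = GRanges()), w$bundle)
  expect_equal(fr0$tags_in_set, 0L)
})

test_that("top-N class enrichment reproduces hand-computable cases", {
  samples <- mkSamples(c(rep("cancer", 4), rep("normal", 6)))
  fr <- setNames(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1), samples$sample_id)
  res <- topNClassEnrichment(fr, samples, n = 4L, class = "cancer")
  expect_equal(res$k, 4)
  expect_equal(res$expected, 4 * 4 / 10)
  expect_equal(res$p, oracleHyperUpper(10, 4, 4, 4), tolerance = 1e-12)
  # k at expectation gives an unremarkable p
  fr2 <- setNames(rev(seq_len(10)), samples$sample_id)
  names(fr2) <- samples$sample_id[c(1, 5, 6, 7, 2, 8, 9, 10, 3, 4)]
  res2 <- topNClassEnrichment(fr2, samples, n = 5L, class = "cancer")
  expect_gt(res2$p, 0.2)
})

test_that("class fraction tests find a planted cancer boost", {
  set.seed(72)
  cl <- c(rep("cancer", 30), rep("normal", 30))
  samples <- mkSamples(cl)
  fr <- setNames(c(rnorm(30, 2), rnorm(30, 1)), samples$sample_id)
  res <- classFractionTests(fr, samples)
  expect_lt(res$p["cancer", "normal"], 0.01)
  expect_gt(res$p["normal", "cancer"], 0.5)
  expect_gt(res$medians["cancer"], res$medians["normal"])
})

test_that("time-course trend follows the decreasing-direction convention", {
  t <- 1:10
  down <- 10 - 0.5 * t
  res <- timecourseTrend(down, t)
  expect_equal(res$direction, "decrease")
  expect_lt(res$p, 1e-12)   # perfect line: p -> 0
  set.seed(73)
  flat <- rnorm(10)
  resF <- timecourseTrend(flat, t)
  expect_gt(ifelse(is.na(resF$p), 1, resF$p), 0.05)
  up <- 0.5 * t + rnorm(10, sd = 0.01)
  resU <- timecourseTrend(up, t)
  expect_equal(resU$direction, "increase")
  expect_true(is.na(resU$p))   # the not-applicable convention
  # noisy decrease: p equals half the regression F-test p
  y <- 10 - 0.5 * t + rnorm(10, sd = 0.5)
  resN <- timecourseTrend(y, t)
  fit <- summary(lm(y ~ t))
  expect_equal(resN$p,
               pf(fit$fstatistic[1], 1, 8, lower.tail = FALSE) / 2,
               ignore_attr = TRUE)
})
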