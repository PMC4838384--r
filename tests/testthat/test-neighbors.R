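test_that("pair classification handles the canonical examples", {
  # 0-based [10000,60000)+ and [61000,70000)+ -> same_downstream, 1000
  a <- rg("chr1", 10001, 60000, "+")
  b <- rg("chr1", 61001, 70000, "+")
  cls <- classifyPair(a, b)
  expect_equal(cls$configuration, "same_downstream")
  expect_equal(cls$distance, 1000)
  expect_equal(cls$bin, "1-5kb")
  # opposite-strand gene whose 3' end faces the vlincRNA 3' end
  b2 <- rg("chr1", 60501, 65000, "-")
  expect_equal(classifyPair(a, b2)$configuration, "opposite_tail_to_tail")
  # facing 5' ends
  a2 <- rg("chr1", 10001, 60000, "-")
  b3 <- rg("chr1", 61001, 70000, "+")
  expect_equal(classifyPair(a2, b3)$configuration, "opposite_head_to_head")
  # overlapping opposite-strand pair: distance 0, first bin
  b4 <- rg("chr1", 50001, 65000, "-")
  cls4 <- classifyPair(a, b4)
  expect_equal(cls4$distance, 0)
  expect_equal(cls4$bin, "0-1kb")
})

test_that("classification is total and agrees with the side-rule oracle", {
  set.seed(61)
  for (rep in 1:150) {
    aS <- sample(1:50000, 1); aE <- aS + sample(1000:40000, 1)
    left <- sample(c(TRUE, FALSE), 1)
    gap <- sample(0:60000, 1)
    if (left) { bE <- aS - gap - 1; bS <- bE - sample(500:8000, 1) }
    else { bS <- aE + gap + 1; bE <- bS + sample(500:8000, 1) }
    if (bS < 1) next
    aStr <- sample(c("+", "-"), 1); bStr <- sample(c("+", "-"), 1)
    a <- rg("chr1", aS, aE, aStr); b <- rg("chr1", bS, bE, bStr)
    cls <- classifyPair(a, b)
    expect_true(cls$configuration %in%
                  c("same_upstream", "same_downstream",
                    "opposite_tail_to_tail", "opposite_head_to_head"))
    expect_equal(cls$configuration,
                 oracleConfig(aS, aE, aStr, bS, bE, bStr))
    expect_equal(cls$distance, oracleGap(aS, aE, bS, bE))
    binWant <- cut(cls$distance,
                   c(-1, 999, 4999, 9999, 19999, 29999, 39999, 49999, Inf),
                   labels = c("0-1kb", "1-5kb", "5-10kb", "10-20kb",
                              "20-30kb", "30-40kb", "40-50kb", ">50kb"))
    expect_equal(cls$bin, as.character(binWant))
  }
})

test_that("neighbor enumeration excludes self-pairs and flags insulators", {
  g <- rg("chr1", c(1000, 30000, 200000), c(5000, 40000, 210000),
          c("+", "+", "-"), tx_id = c("g1", "g2", "g3"))
  ins <- rg("chr1", 10000, 11000)
  pr <- neighborPairs(g, g, ins, maxGap = 1e5)
  expect_false(any(pr$a_id == pr$b_id))
  p12 <- pr[pr$a_id == "g1" & pr$b_id == "g2", ]
  expect_true(p12$insulator_separated)
  expect_equal(p12$configuration, "same_downstream")
  # beyond the horizon: g1-g3 gap is 159 999 > 1e5
  expect_false(any(pr$a_id == "g1" & pr$b_id == "g3"))
})

test_that("two-stage medians match a direct nested computation", {
  # three neighbors with rhos (0.1, 0.2, 0.9) -> per-feature median 0.2
  expect_equal(oracleTwoStageMedian(c("a", "a", "a"), c(0.1, 0.2, 0.9)), 0.2)
  set.seed(62)
  n <- 60
  m <- matrix(rnorm(n * 30), n, 30,
              dimnames = list(paste0("f", 1:n), NULL))
  aId <- paste0("f", sample(1:10, 40, replace = TRUE))
  bId <- paste0("f", sample(11:60, 40, replace = TRUE))
  pairs <- data.frame(a_id = aId, b_id = bId,
                      configuration = "same_upstream", distance = 500,
                      bin = "0-1kb", insulator_separated = FALSE,
                      stringsAsFactors = FALSE)
  tab <- correlationTable(m, pairs, "gene_gene")
  cell <- tab[tab$configuration == "same_upstream" & tab$bin == "0-1kb" &
                tab$stratum == "all", ]
  rho <- pairRho(m, aId, bId)
  expect_equal(cell$median_rho, oracleTwoStageMedian(aId, rho))
  expect_equal(cell$n_pairs, 40)
  # empty cells carry n = 0 and no median
  empty <- tab[tab$bin == "40-50kb" & tab$stratum == "all" &
                 tab$configuration == "same_upstream", ]
  expect_equal(empty$n_pairs, 0)
  expect_true(is.na(empty$median_rho))
})

test_that("insulator strata are bookkeeping only: rho unchanged, counts move", {
  set.seed(63)
  m <- matrix(rnorm(20 * 40), 20, 40,
              dimnames = list(paste0("f", 1:20), NULL))
  pairs <- data.frame(a_id = "f1", b_id = "f2",
                      configuration = "same_upstream", distance = 500,
                      bin = "0-1kb", insulator_separated = FALSE,
                      stringsAsFactors = FALSE)
  t1 <- correlationTable(m, pairs, minPairs = 1L)
  pairs$insulator_separated <- TRUE
  t2 <- correlationTable(m, pairs, minPairs = 1L)
  pick <- function(t, s) t[t$configuration == "same_upstream" &
                             t$bin == "0-1kb" & t$stratum == s, ]
  expect_equal(pick(t1, "not_separated")$n_pairs, 1)
  expect_equal(pick(t1, "separated")$n_pairs, 0)
  expect_equal(pick(t2, "separated")$n_pairs, 1)
  expect_equal(pick(t2, "not_separated")$n_pairs, 0)
  expect_equal(pick(t1, "all")$median_rho, pick(t2, "all")$median_rho)
  # strata counts always sum to the all-stratum count
  w <- tinyWorld()
  pr <- neighborPairs(vlincRanges(w$bundle), geneBodies(w$bundle),
                      insulatorElements(w$bundle))
  expr <- w$latent$abundance
  tab <- correlationTable(expr, pr)
  for (cf in unique(tab$configuration)) for (bn in unique(tab$bin)) {
    cell <- tab[tab$configuration == cf & tab$bin == bn, ]
    expect_equal(cell$n_pairs[cell$stratum == "all"],
                 cell$n_pairs[cell$stratum == "separated"] +
                   cell$n_pairs[cell$stratum == "not_separated"])
  }
})

test_that("group comparison delegates to the one-sided tests", {
  set.seed(64)
  a <- rnorm(50, 0.4, 0.1); b <- rnorm(50, 0.1, 0.1)
  expect_lt(comparePairGroups(a, b, "mww")$p, 0.01)
  expect_lt(comparePairGroups(a, b, "ks")$p, 0.01)
  same <- rnorm(30)
  expect_gt(comparePairGroups(same, same, "ks")$p, 0.9)
  # NAs are dropped and reported in the counts
  res <- comparePairGroups(c(a, NA), b, "mww")
  expect_equal(res$nA, 50)
})
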