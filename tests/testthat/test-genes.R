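mkVl <- function(s, e, strand = "+", id = "v1")
  rg("chr1", s, e, strand, vlinc_id = id)

test_that("standalone designation handles the canonical layouts", {
  v <- mkVl(200000, 280000)
  # one same-strand gene 10 kb upstream, no insulator: blocked
  g <- rg("chr1", 180000, 189999, "+", tx_id = "g1")
  d <- designateStandalone(v, g, GRanges())
  expect_false(d$standalone)
  expect_equal(d$reason, "not_standalone")
  # same gene separated by an insulator: standalone via insulator clearance
  ins <- rg("chr1", 193000, 194000)
  d2 <- designateStandalone(v, g, ins)
  expect_true(d2$standalone)
  expect_equal(d2$reason, "far_one_insulator_other")
  # genes on both sides, both separated
  g2 <- c(g, rg("chr1", 300000, 310000, "+", tx_id = "g2"))
  ins2 <- c(ins, rg("chr1", 285000, 286000))
  d3 <- designateStandalone(v, g2, ins2)
  expect_equal(d3$reason, "insulator_both_sides")
  # no genes within 50 kb at all
  d4 <- designateStandalone(v, rg("chr1", 500000, 510000, "+", tx_id = "g"),
                            GRanges())
  expect_equal(d4$reason, "far_both_sides")
  # opposite-strand gene never blocks
  d5 <- designateStandalone(v, rg("chr1", 180000, 189999, "-", tx_id = "g"),
                            GRanges())
  expect_true(d5$standalone)
  # gene at exactly 50 kb is "within" and blocks (inclusive rule)
  gx <- rg("chr1", 330001, 340000, "+", tx_id = "g")  # gap exactly 50 000
  expect_false(designateStandalone(v, gx, GRanges())$standalone)
  expect_true(designateStandalone(v, gx, GRanges(),
                                  inclusive = FALSE)$standalone)
})

test_that("designation agrees with an exhaustive per-gene oracle", {
  set.seed(51)
  for (rep in 1:100) {
    vS <- 400000; vE <- 480000; vStr <- sample(c("+", "-"), 1)
    v <- mkVl(vS, vE, vStr)
    ng <- sample(0:6, 1)
    gS <- sample(seq(250000, 650000, by = 500), ng)
    gE <- gS + sample(5000:20000, max(1, ng), replace = TRUE)[seq_len(ng)]
    gStr <- sample(c("+", "-"), ng, replace = TRUE)
    genes <- if (ng) rg("chr1", gS, gE, gStr,
                        tx_id = paste0("g", seq_len(ng))) else GRanges()
    ni <- sample(0:6, 1)
    iS <- sample(seq(250000, 650000, by = 333), ni)
    ins <- if (ni) rg("chr1", iS, iS + 999) else GRanges()
    got <- designateStandalone(v, genes, ins)
    # oracle: per side in genomic coordinates, then strand-agnostic AND
    blockLeft <- blockRight <- FALSE
    hasLeft <- hasRight <- FALSE
    for (j in seq_len(ng)) {
      if (gStr[j] != vStr) next
      gap <- if (gS[j] > vE) gS[j] - vE - 1
             else if (vS > gE[j]) vS - gE[j] - 1 else 0
      overlapping <- gS[j] <= vE && gE[j] >= vS
      if (gap > 50000 && !overlapping) next
      sep <- oracleSeparated(vS, vE, gS[j], gE[j], iS, iS + 999) &&
        !overlapping
      onLeft <- gE[j] < vS || overlapping
      onRight <- gS[j] > vE || overlapping
      if (onLeft) { hasLeft <- TRUE; if (!sep) blockLeft <- TRUE }
      if (onRight) { hasRight <- TRUE; if (!sep) blockRight <- TRUE }
    }
    wantStandalone <- !blockLeft && !blockRight
    expect_equal(got$standalone, wantStandalone)
    if (wantStandalone) {
      want <- if (!hasLeft && !hasRight) "far_both_sides"
        else if (hasLeft && hasRight) "insulator_both_sides"
        else "far_one_insulator_other"
      expect_equal(got$reason, want)
    }
  }
})

test_that("removing insulators never increases the standalone count", {
  w <- tinyWorld()
  withIns <- designateStandalone(vlincRanges(w$bundle),
                                 geneBodies(w$bundle),
                                 insulatorElements(w$bundle))
  without <- designateStandalone(vlincRanges(w$bundle),
                                 geneBodies(w$bundle), GRanges())
  expect_lte(sum(without$standalone), sum(withIns$standalone))
  # raising the threshold can only shrink the far-both-sides category
  wide <- designateStandalone(vlincRanges(w$bundle), geneBodies(w$bundle),
                              insulatorElements(w$bundle),
                              threshold = 80000L)
  expect_lte(sum(wide$reason == "far_both_sides"),
             sum(withIns$reason == "far_both_sides"))
})

test_that("planted clearances are recovered exactly on the fixture", {
  w <- tinyWorld()
  sim <- metadata(w$bundle)$sim
  d <- designateStandalone(vlincRanges(w$bundle), geneBodies(w$bundle),
                           insulatorElements(w$bundle))
  rownames(d) <- d$vlinc_id
  plan <- sim$plan[sim$plan$pair_type == "vlinc_gene", ]
  sameStrand <- plan$configuration %in% c("same_upstream", "same_downstream")
  # same-strand gene within 50 kb, no insulator: blocked
  expect_true(all(!d[plan$a_id[sameStrand & !plan$insulator], "standalone"]))
  # same-strand gene separated by insulator: cleared
  expect_true(all(d[plan$a_id[sameStrand & plan$insulator], "standalone"]))
  # opposite-strand neighbors never block
  expect_true(all(d[plan$a_id[!sameStrand], "standalone"]))
})

test_that("gene building merges same-strand overlaps and preserves bases", {
  a <- mkVl(1000, 5000, "+", "v1")
  b <- mkVl(4000, 9000, "+", "v2")
  g <- buildGenes(c(a, b))
  expect_equal(length(g), 1L)
  expect_setequal(unlist(g$member_ids), c("v1", "v2"))
  # disjoint input passes through
  g2 <- buildGenes(c(mkVl(1000, 5000, "+", "v1"),
                     mkVl(9000, 12000, "+", "v2")))
  expect_equal(length(g2), 2L)
  expect_equal(length(buildGenes(GRanges())), 0L)
  # random merge equals base-union oracle, gene count <= input count
  set.seed(52)
  for (rep in 1:60) {
    n <- sample(2:60, 1)
    s <- sample(1:8000, n, replace = TRUE)
    e <- s + sample(100:900, n, replace = TRUE)
    st <- sample(c("+", "-"), n, replace = TRUE)
    vl <- rg("chr1", s, e, st, vlinc_id = paste0("v", seq_len(n)))
    g <- buildGenes(vl)
    expect_lte(length(g), n)
    orc <- oracleMerge(rep("chr1", n), s, e, st)
    for (key in names(orc)) {
      stx <- strsplit(key, " ")[[1]][2]
      sel <- as.character(strand(g)) == stx
      expect_equal(sum(sel), orc[[key]]$n)
      expect_equal(sum(width(g[sel])), orc[[key]]$bases)
    }
  }
})
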