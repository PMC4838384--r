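mkTags <- function(pos, strand, count = rep(1L, length(pos)),
                   chr = "chr1", informative = 1000) {
  TagSet("s", GRanges(chr, IRanges(pos, width = 1), strand = strand,
                      count = count), informative)
}

test_that("tag counting honors borders, strand and multiplicity", {
  frag <- rg("chr1", c(100, 300), c(199, 399), "+")
  # 5' end exactly on the fragment start is counted
  expect_equal(countTags(mkTags(100, "+"), frag), 1L)
  expect_equal(countTags(mkTags(199, "+"), frag), 1L)
  expect_equal(countTags(mkTags(200, "+"), frag), 0L)
  # opposite strand inside the fragment is not counted
  expect_equal(countTags(mkTags(150, "-"), frag), 0L)
  # multiplicities sum
  expect_equal(countTags(mkTags(c(150, 320), c("+", "+"), c(3L, 2L)), frag),
               5L)
  # unstranded feature counts both strands
  fragU <- rg("chr1", 100, 199, "*")
  expect_equal(countTags(mkTags(c(150, 160), c("+", "-")), fragU), 2L)
})

test_that("tag counting agrees with a double-loop oracle on random input", {
  set.seed(21)
  for (rep in 1:100) {
    nt <- sample(1:1000, 1)
    pos <- sample(1:5000, nt, replace = TRUE)
    str <- sample(c("+", "-"), nt, replace = TRUE)
    cnt <- sample(1:3, nt, replace = TRUE)
    ni <- sample(1:5, 1)
    iS <- sample(1:4500, ni); iE <- iS + sample(50:500, ni, replace = TRUE)
    iStr <- sample(c("+", "-", "*"), 1)
    # aggregate duplicates the same way the container does
    ts <- mkTags(pos, str, cnt)
    frag <- rg("chr1", iS, iE, iStr)
    expect_equal(countTags(ts, frag),
                 oracleCountTags(pos, str, cnt, iS, iE,
                                 rep(iStr, ni)))
  }
})

test_that("counts are invariant to splitting a sample into channels", {
  w <- tinyWorld()
  ts <- w$tagsets[[2]]
  tags <- tagPositions(ts)
  half <- seq_len(length(tags)) %% 2 == 0
  ch1 <- TagSet("s", tags[half], informativeReads(ts) / 2)
  ch2 <- TagSet("s", tags[!half], informativeReads(ts) / 2)
  merged <- mergeChannels(list(ch1, ch2))
  frag <- effectiveVlincSpace(vlincRanges(w$bundle)[3], w$bundle)$fragments
  expect_equal(countTags(merged, frag), countTags(ts, frag))
  expect_equal(informativeReads(merged), informativeReads(ts))
})

test_that("effective length follows the masking rules", {
  # 100 kb vlincRNA, one 5 kb exon mask and one 1 kb rRNA: 94 kb left
  genes <- rg("chr1", 200001, 230000, "+", tx_id = "g1")
  exons <- GRangesList(rg("chr1", 210001, 215000, "+"))
  b <- AnnotationBundle(
    genes = genes, exons = exons,
    vlincs = rg("chr1", 200001, 300000, "+", vlinc_id = "v1"),
    rrnaRepeats = rg("chr1", 250001, 251000))
  ev <- effectiveVlincSpace(vlincRanges(b)[1], b)
  expect_equal(ev$length, 94000)
  # gene exonic length is the sum of exon widths
  expect_equal(sum(width(geneExons(b)[[1]])), 5000)
})

test_that("RPKM applies the per-kind scalings and is linear", {
  expect_equal(rpkm(100, 1e7, 1000, "gene"), 10)
  expect_equal(rpkm(100, 1e7, 1000, "vlinc"), 1000)
  expect_equal(rpkm(0, 1e7, 1000, "gene"), 0)
  expect_error(rpkm(5, 0, 100, "gene"), "informative")
  expect_error(rpkm(5, 100, 0, "gene"), "length")
  set.seed(2)
  raw <- runif(20, 0, 500); inf <- 1e6; len <- 2000
  expect_equal(rpkm(3 * raw, inf, len, "gene"), 3 * rpkm(raw, inf, len, "gene"))
  expect_equal(rpkm(raw, 2 * inf, len, "gene"), rpkm(raw, inf, len, "gene") / 2)
  expect_equal(rpkm(raw, inf, 2 * len, "gene"), rpkm(raw, inf, len, "gene") / 2)
})

test_that("matrix quantification equals independent per-cell recomputation", {
  w <- tinyWorld()
  sim <- metadata(w$bundle)$sim
  expr <- suppressMessages(quantifyExpression(w$bundle, w$tagsets,
                                              mirnas = sim$mirnas))
  m <- rpkmValues(expr)
  lens <- setNames(effectiveLengths(expr), rownames(expr))
  kinds <- setNames(featureKind(expr), rownames(expr))
  set.seed(31)
  feats <- sample(rownames(m), 10)
  smps <- sample(colnames(m), 2)
  for (f in feats) for (s in smps) {
    ts <- w$tagsets[[s]]
    space <- if (kinds[f] == "gene") {
      i <- match(f, mcols(geneBodies(w$bundle))$tx_id)
      ex <- granges(geneExons(w$bundle)[[i]])
      strand(ex) <- as.character(strand(geneBodies(w$bundle)[i]))
      ex
    } else if (kinds[f] == "vlinc") {
      i <- match(f, mcols(vlincRanges(w$bundle))$vlinc_id)
      effectiveVlincSpace(vlincRanges(w$bundle)[i], w$bundle)$fragments
    } else {
      i <- match(f, mcols(sim$mirnas)$mirna_id)
      mm <- sim$mirnas[i]
      GRanges(seqnames(mm), IRanges(start(mm) - 1000, end(mm) + 1000),
              strand = strand(mm))
    }
    raw <- countTags(ts, space)
    want <- rpkm(raw, informativeReads(ts), lens[f], kinds[f])
    expect_equal(unname(m[f, s]), unname(want), tolerance = 1e-9)
  }
})

test_that("internal counting tracks a body-read reference better than flank counting", {
  w <- tinyWorld()
  sim <- metadata(w$bundle)$sim
  internal <- suppressMessages(quantifyExpression(w$bundle, w$tagsets))
  flank <- suppressMessages(quantifyExpression(w$bundle, w$tagsets,
                                               mode = "flank"))
  vIds <- intersect(rownames(internal)[featureKind(internal) == "vlinc"],
                    rownames(flank))
  truth <- w$latent$abundance[vIds, ]  # body abundance stands in for RNA-seq
  s <- colnames(rpkmValues(internal))[3]
  rhoInt <- spearmanRho(rpkmValues(internal)[vIds, s], truth[, s])
  rhoFl <- spearmanRho(rpkmValues(flank)[vIds, s], truth[, s])
  expect_gt(rhoInt, rhoFl)
})

test_that("RNA-seq counting applies the half-tag border rule", {
  frag <- rg("chr1", c(100, 300), c(199, 399), "+")
  expect_equal(rnaseqCount(rg("chr1", 120, 150, "+"), frag), 1)
  expect_equal(rnaseqCount(rg("chr1", 90, 120, "+"), frag), 0.5)
  expect_equal(rnaseqCount(rg("chr1", 120, 150, "-"), frag), 0)
  set.seed(22)
  for (rep in 1:60) {
    nr <- sample(1:200, 1)
    rS <- sample(1:2000, nr, replace = TRUE)
    rE <- rS + sample(20:80, nr, replace = TRUE)
    iS <- c(500, 1200); iE <- c(900, 1600)
    got <- rnaseqCount(rg("chr1", rS, rE, "+"), rg("chr1", iS, iE, "+"))
    want <- 0
    for (i in seq_len(nr)) {
      insideAny <- any(rS[i] >= iS & rE[i] <= iE)
      touchAny <- any(rS[i] <= iE & rE[i] >= iS)
      want <- want + if (insideAny) 1 else if (touchAny) 0.5 else 0
    }
    expect_equal(got, want)
  }
})

test_that("strand calling picks the majority strand and flags ties", {
  v <- rg("chr1", 100, 999)
  plus <- mkTags(sample(100:999, 10), rep("+", 10))
  mix <- mkTags(c(sample(100:999, 10), sample(100:999, 3)),
                c(rep("+", 10), rep("-", 3)))
  expect_equal(callStrand(v, mix), "+")
  expect_equal(callStrand(v, TagSet("s", GRanges(), 10)), "*")
  tie <- mkTags(c(150, 160), c("+", "-"))
  expect_equal(callStrand(v, tie), "*")
  set.seed(23)
  for (rep in 1:50) {
    np <- sample(0:20, 1); nm <- sample(0:20, 1)
    ts <- mkTags(sample(100:999, np + nm, replace = TRUE),
                 c(rep("+", np), rep("-", nm)))
    want <- if (np > nm) "+" else if (nm > np) "-" else "*"
    expect_equal(callStrand(v, ts), want)
  }
})

test_that("the 5'-density profile bins tags in transcript orientation", {
  vl <- rg("chr1", c(50000, 70000), c(60000, 80000), c("+", "-"),
           vlinc_id = c("vp", "vm"))
  # all tags exactly at the annotated 5' base -> bin 11
  ts <- mkTags(c(50000, 80000), c("+", "-"))
  prof <- tssDensityProfile(vl, list(ts))
  expect_equal(prof[11], 2)
  expect_equal(sum(prof), 2)
  # no tags -> zero vector
  expect_equal(sum(tssDensityProfile(vl, list(TagSet("e", GRanges(), 1)))), 0)
  # outlier exclusion removes the feature's contribution
  prof2 <- tssDensityProfile(vl, list(ts), exclude = "vm")
  expect_equal(sum(prof2), 1)
  # random placement matches a direct binning oracle (plus-strand feature)
  set.seed(24)
  for (rep in 1:40) {
    pos <- sample(45000:54999, 50, replace = TRUE)
    tsr <- mkTags(pos, rep("+", 50))
    got <- tssDensityProfile(vl[1], list(tsr))
    want <- tabulate((pos - 45000) %/% 500 + 1, 20)
    expect_equal(got, as.numeric(want))
  }
})
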