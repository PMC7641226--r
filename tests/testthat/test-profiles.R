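# A small deterministic genome on one 100 kb chromosome for profile
# tests: one gene per strand, away from the edges.
profGenes <- function() {
  geneModels(c("gp", "gm"), "c1", c(30000, 60000), c(40000, 70000),
    c("+", "-"))
}

test_that("a uniform track yields a flat TSS profile", {
  tr <- SignalTrack(list(c1 = rep(2.5, 1000)), step = 100L)
  pm <- tssProfile(tr, profGenes(), flank = 5000, bin = 100)
  expect_true(all(abs(meanProfile(pm) - 2.5) < 1e-12))
})

test_that("mirror-image signal on opposite strands gives identical rows", {
  n <- 1000
  v <- rep(0, n)
  # + gene TSS at 30000 (bin 301); put an asymmetric pattern around it
  v[301:305] <- 5   # downstream of + TSS
  v[298:300] <- 1   # upstream of + TSS
  # - gene TSS at 70000 (bin 700 boundary); mirrored pattern
  v[696:700] <- 5   # downstream of - TSS (decreasing coords)
  v[701:703] <- 1   # upstream of - TSS
  tr <- SignalTrack(list(c1 = v), step = 100L)
  pm <- tssProfile(tr, profGenes(), flank = 2000, bin = 100)
  expect_equal(unname(profileValues(pm)["gp", ]),
    unname(profileValues(pm)["gm", ]))
})

test_that("TSS profile rows match a direct window-sum oracle", {
  set.seed(41)
  v <- runif(1000, 0, 3)
  tr <- SignalTrack(list(c1 = v), step = 100L)
  g <- profGenes()[1]
  pm <- tssProfile(tr, g, flank = 1000, bin = 200)
  tss <- 30000
  for (k in seq_along(profilePositions(pm))) {
    off <- profilePositions(pm)[k] - 100  # bin start offset
    want <- oracleWindowSum(v, 100, tss + off, tss + off + 200) / 200
    expect_equal(unname(profileValues(pm)[1, k]), want)
  }
})

test_that("scaled body profiles align signal fractions across lengths", {
  # uniform signal -> flat profile
  tr <- SignalTrack(list(c1 = rep(1.5, 1000)), step = 100L)
  pm <- scaledBodyProfile(tr, profGenes(), n_body_bins = 20, flank = 0)
  expect_true(all(abs(profileValues(pm) - 1.5) < 1e-12))
  # signal on the first half of each body only (strand-aware)
  v <- rep(0, 1000)
  v[301:350] <- 2          # first half of + gene [30k,40k)
  v[651:700] <- 2          # first half of - gene body = [65k,70k)
  tr2 <- SignalTrack(list(c1 = v), step = 100L)
  pm2 <- scaledBodyProfile(tr2, profGenes(), n_body_bins = 20, flank = 0)
  expect_true(all(abs(profileValues(pm2)[, 1:10] - 2) < 1e-12))
  expect_true(all(abs(profileValues(pm2)[, 11:20]) < 1e-12))
  # per-fraction means match a per-bp oracle for uneven bin edges
  set.seed(42)
  v3 <- runif(1000, 0, 2)
  tr3 <- SignalTrack(list(c1 = v3), step = 100L)
  g <- geneModels("gx", "c1", 30000, 30750, "+")  # 750 bp, 3 bins of 250
  pm3 <- scaledBodyProfile(SignalTrack(list(c1 = rep(v3, each = 100)),
    step = 1L), g, n_body_bins = 3, flank = 0)
  perbp <- rep(v3, each = 100)
  want <- c(mean(perbp[30001:30250]), mean(perbp[30251:30500]),
    mean(perbp[30501:30750]))
  expect_equal(unname(profileValues(pm3)[1, ]), want)
  # genes shorter than n_body_bins x step are skipped with a warning
  gshort <- geneModels("gs", "c1", 100, 1100, "+")
  expect_warning(scaledBodyProfile(tr, gshort, n_body_bins = 20,
    flank = 0), "skipped")
})

test_that("pausing index is the promoter/body ratio of signal sums", {
  # uniform density d over a 3300 bp gene: 330d / 3000d = 0.11
  tr <- SignalTrack(list(c1 = rep(2, 40000)), step = 1L)
  g <- geneModels("g1", "c1", 10000, 13300, "+")
  expect_equal(pausingIndex(tr, g), 0.11)
  gm <- geneModels("g2", "c1", 10000, 13300, "-")
  expect_equal(pausingIndex(tr, gm), 0.11)
  # promoter-only signal leaves the body sum 0: undefined
  v <- rep(0, 40000); v[9971:10300] <- 3
  expect_true(is.na(pausingIndex(SignalTrack(list(c1 = v), 1L), g)))
  # random track vs per-bp oracle, both strands
  set.seed(43)
  v2 <- runif(40000)
  tr2 <- SignalTrack(list(c1 = v2), step = 1L)
  expect_equal(pausingIndex(tr2, g),
    sum(v2[9971:10300]) / sum(v2[10301:13300]))
  expect_equal(pausingIndex(tr2, gm),
    sum(v2[13001:13330]) / sum(v2[10001:13000]))
})

test_that("PTB ratio uses the 3 kb promoter windows", {
  tr <- SignalTrack(list(c1 = rep(1, 60000)), step = 1L)
  g <- geneModels("g1", "c1", 20000, 50000, "+")  # 30 kb
  expect_equal(ptbRatio(tr, g), 6000 / 27000)
  set.seed(44)
  v <- runif(60000)
  tr2 <- SignalTrack(list(c1 = v), step = 1L)
  expect_equal(ptbRatio(tr2, g),
    sum(v[17001:23000]) / sum(v[23001:50000]))
})

test_that("pausing and PTB ratios are scale invariant", {
  set.seed(45)
  v <- runif(40000)
  g <- geneModels("g1", "c1", 10000, 13300, "+")
  a <- pausingIndex(SignalTrack(list(c1 = v), 1L), g)
  b <- pausingIndex(SignalTrack(list(c1 = v * 7.3), 1L), g)
  expect_equal(a, b)
})

test_that("eligibility requires strictly detectable Pol II on both windows", {
  st <- data.frame(gene_id = c("a", "b", "c"),
    pol2_promoter_mean = c(0.02, 0.02, 0.01),
    pol2_body_mean = c(0.02, 0.005, 0.02))
  out <- eligibilityFilter(st)
  expect_equal(out$gene_id, "a")  # b fails body, c sits on the floor
})

test_that("motif tracks are binary indicators without double counting", {
  occ <- data.frame(chrom = "c1", start = c(0, 5), end = c(10, 15))
  tr <- motifTrack(occ)
  expect_equal(trackValues(tr)$c1, rep(1, 15))
  expect_equal(trackValues(motifTrack(occ[0, ],
    chrom_lengths = c(c1 = 5)))$c1, rep(0, 5))
  # random sets vs per-bp membership oracle
  set.seed(46)
  s <- sample(0:180, 25); occ2 <- data.frame(chrom = "c1", start = s,
    end = s + sample(3:20, 25, TRUE))
  tr2 <- motifTrack(occ2, chrom_lengths = c(c1 = 220))
  want <- logical(220)
  for (i in seq_len(nrow(occ2)))
    want[(occ2$start[i] + 1):occ2$end[i]] <- TRUE
  expect_equal(trackValues(tr2)$c1, as.numeric(want))
})

test_that("motif enrichment detects body-restricted placement", {
  spec <- syntheticSpec(seed = 9, n_genes = 60, chrom_length = 6e6,
    frac_bgrd = 0.2, frac_fgrd = 0)
  genes <- makeGenome(spec)
  pl <- choosePlantedDomains(genes, spec)
  bg <- genes[genes$gene_id %in% pl$bgrd]
  ctrl <- genes[!genes$gene_id %in% pl$bgrd][1:12]
  expect_equal(motifFoldEnrichment(
    motifTrack(data.frame(chrom = "chrS", start = seq(0, 5.9e6, 1e4),
      end = seq(0, 5.9e6, 1e4) + 500),
      chrom_lengths = c(chrS = 6e6)), bg, bg, 10, 0), 1)
  # motifs only inside BGRD gene bodies
  occ <- data.frame(chrom = "chrS",
    start = start(bg) + floor(width(bg) * 0.4),
    end = start(bg) + floor(width(bg) * 0.4) + 2000)
  mt <- motifTrack(occ, chrom_lengths = c(chrS = 6e6))
  expect_error(motifFoldEnrichment(mt, bg, ctrl, 10, 0), "control density")
  # add sparse background so the control density is nonzero
  occ2 <- rbind(occ, data.frame(chrom = "chrS",
    start = seq(1000, 5.9e6, 5e4), end = seq(1000, 5.9e6, 5e4) + 50))
  mt2 <- motifTrack(occ2, chrom_lengths = c(chrS = 6e6))
  expect_gt(motifFoldEnrichment(mt2, bg, ctrl, 10, 0), 2)
  # uniform dense placement is near fold 1
  u <- seq(0, 5.99e6, 2000)
  mt3 <- motifTrack(data.frame(chrom = "chrS", start = u, end = u + 1000),
    chrom_lengths = c(chrS = 6e6))
  expect_lt(abs(motifFoldEnrichment(mt3, bg, ctrl, 10, 0) - 1), 0.2)
})

test_that("reversing the genome leaves TSS profiles unchanged", {
  set.seed(47)
  L <- 100000L
  v <- runif(L / 100, 0, 3)
  tr <- SignalTrack(list(c1 = v), step = 100L)
  g <- profGenes()
  fwd <- tssProfile(tr, g, flank = 3000, bin = 100)
  # mirror: coordinates x -> L - x, strands flipped, track reversed
  gr <- geneModels(g$gene_id, "c1", L - end(g), L - (start(g) - 1L),
    c("-", "+"))
  trr <- SignalTrack(list(c1 = rev(v)), step = 100L)
  rev_pm <- tssProfile(trr, gr, flank = 3000, bin = 100)
  expect_equal(profileValues(rev_pm), profileValues(fwd))
})

test_that("rank slices pick disjoint top, median and bottom sets", {
  v <- stats::setNames(1:100, sprintf("g%03d", 1:100))
  sl <- rankSlices(v, 10)
  expect_equal(sl$top, sprintf("g%03d", 100:91))
  expect_equal(sl$bottom, sprintf("g%03d", 10:1))
  expect_length(intersect(sl$top, sl$median), 0L)
})
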