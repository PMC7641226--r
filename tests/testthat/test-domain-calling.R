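test_that("peak aggregation sums widths and takes the tallest height", {
  g <- geneModels("g1", "chr1", 0, 100, "+")
  p <- peakRanges(c("chr1", "chr1"), c(10, 50), c(20, 90), c(2, 5))
  st <- genePeakStats(g, p)
  expect_equal(st$width_sum, 50)
  expect_equal(st$height_max, 5)
  expect_equal(st$coverage, 0.5)
})

test_that("clipping controls whether peaks count beyond gene bounds", {
  g <- geneModels("g1", "chr1", 0, 100, "+")
  p <- peakRanges("chr1", -50, 150, 1)
  expect_equal(genePeakStats(g, p, clip = FALSE)$width_sum, 200)
  expect_equal(genePeakStats(g, p, clip = TRUE)$width_sum, 100)
  # a gene with no peaks gets zeros, not an error
  g2 <- geneModels(c("g1", "g2"), "chr1", c(0, 500), c(100, 600), "+")
  st <- genePeakStats(g2, p)
  expect_equal(st$width_sum[2], 0)
  expect_equal(st$height_max[2], 0)
})

test_that("peak aggregation matches the exhaustive all-pairs oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    n_g <- 50; n_p <- 120
    gs <- sort(sample(0:49000, n_g)) * 2
    g <- geneModels(sprintf("g%03d", 1:n_g),
      sample(c("chrA", "chrB"), n_g, TRUE), gs,
      gs + sample(500:5000, n_g, TRUE), "+")
    ps <- sample(0:100000, n_p)
    p <- peakRanges(sample(c("chrA", "chrB"), n_p, TRUE), ps,
      ps + sample(50:4000, n_p, TRUE), runif(n_p, 0, 10))
    for (clip in c(FALSE, TRUE)) {
      got <- genePeakStats(g, p, clip = clip)
      want <- oracleGenePeakStats(g, p, clip = clip)
      expect_equal(got$width_sum, want$width_sum)
      expect_equal(got$height_max, want$height_max)
    }
  }
})

test_that("a perfect right angle turns at the last zero", {
  v <- c(rep(0, 99), 5e5)
  tp <- findTurningPoint(v)
  expect_equal(tp@rank_index, 98L)
  expect_equal(widthAtTurn(tp), 0)
})

test_that("turning point matches a brute-force distance scan", {
  for (seed in 4:6) {
    set.seed(seed)
    v <- sort(exp(runif(200, 0, 10)))  # convex-ish L curve
    tp <- findTurningPoint(v)
    want <- oracleKnee(v)
    expect_equal(tp@rank_index, want$rank_index)
    expect_equal(widthAtTurn(tp), want$width)
  }
})

test_that("knee rank is invariant to affine rescaling of the widths", {
  set.seed(7)
  v <- c(rexp(300, 1 / 2000), rexp(100, 1 / 1e5))
  tp <- findTurningPoint(v)
  tp_scaled <- findTurningPoint(v * 3.7)
  tp_shift <- findTurningPoint(v + 12345)
  expect_equal(tp_scaled@rank_index, tp@rank_index)
  expect_equal(tp_shift@rank_index, tp@rank_index)
  expect_equal(widthCutoff(tp_scaled), widthCutoff(tp) * 3.7)
})

test_that("degenerate width curves are rejected", {
  expect_error(findTurningPoint(rep(5, 10)), "degenerate")
  expect_error(findTurningPoint(c(1, 2)), "at least 3")
})

test_that("domain classification respects cutoff, precedence and seed", {
  set.seed(1)
  st <- data.frame(gene_id = sprintf("g%02d", 1:10),
    length = rep(1000, 10),
    width_sum = c(900, 800, 700, 50, 40, 30, 20, 10, 5, 0),
    height_max = c(9, 1, 1, 8, 7, 1, 1, 1, 1, 1),
    coverage = 0, domain_class = "none", group = "unassigned")
  tp <- TurningPoint(5, 100, 2)  # cutoff 200
  cl <- classifyDomains(st, tp, n_top = 3, seed = 1)
  expect_equal(sort(cl$bgrd), c("g01", "g02", "g03"))
  # g01 is top-height too but BGRD wins; FGRD fills from the rest
  expect_false("g01" %in% cl$fgrd)
  expect_equal(sort(cl$fgrd), c("g04", "g05", "g06"))
  expect_length(intersect(cl$bgrd, cl$fgrd), 0L)
  expect_length(cl$control, 3L)
  expect_length(intersect(cl$control, c(cl$bgrd, cl$fgrd)), 0L)
  # cutoff bites: raise it so only g01 qualifies
  cl2 <- classifyDomains(st, TurningPoint(5, 450, 2), n_top = 3, seed = 1)
  expect_equal(cl2$bgrd, "g01")
  # control is reproducible under the seed
  cl3 <- classifyDomains(st, tp, n_top = 3, seed = 1)
  expect_identical(cl$control, cl3$control)
  expect_error(classifyDomains(st, tp, n_top = 11), "n_top")
})

test_that("coverage boundary falls in the valley of a bimodal mixture", {
  set.seed(11)
  v <- c(rnorm(2000, 0.05, 0.01), rnorm(2000, 0.6, 0.05))
  v <- v[v > 0]
  b <- coverageBoundary(v)
  expect_gt(b, 0.1)
  expect_lt(b, 0.4)
  # analytic valley of the equal-weight mixture density
  dens <- function(x) 0.5 * dnorm(x, 0.05, 0.01) + 0.5 * dnorm(x, 0.6, 0.05)
  valley <- optimize(dens, c(0.05, 0.6))$minimum
  expect_lt(abs(b - valley), 0.15)
})

test_that("coverage boundary handles point masses and unimodal input", {
  b <- coverageBoundary(c(rep(0.1, 50), rep(0.9, 50)))
  expect_gt(b, 0.1)
  expect_lt(b, 0.9)
  expect_error(coverageBoundary(rep(0.5, 100)), "distinct")
  set.seed(2)
  expect_error(coverageBoundary(abs(rnorm(5000, 0.5, 0.01))), "unimodal")
})

test_that("gene groups partition the universe around the BGRD length floor", {
  st <- data.frame(
    gene_id = c("a", "b", "c", "d", "e"),
    length = c(150e3, 101e3, 120e3, 120e3, 50e3),
    width_sum = c(140e3, 130e3, 0, 0, 0),
    height_max = 0,
    coverage = c(0.9, 0.95, 0.6, 0.05, 0.2),
    domain_class = "none", group = "unassigned")
  out <- assignGeneGroups(st, c("a", "b"), boundary = 0.14)
  expect_equal(attr(out, "min_bgrd_length"), 101e3)
  expect_equal(out$group, c("a1", "a1", "a2", "b", "c"))
  # partition: every gene in exactly one group
  expect_true(all(out$group %in% c("a1", "a2", "b", "c")))
  expect_error(assignGeneGroups(st, character(0), 0.14), "empty")
})

test_that("intron fraction equals one minus exonic fraction", {
  g <- geneModels("g1", "chr1", 0, 100, "+", exons = list(cbind(0, 100)))
  expect_equal(intronFraction(g), 0)
  g2 <- geneModels("g2", "chr1", 0, 100, "+",
    exons = list(cbind(c(0, 50), c(10, 60))))
  expect_equal(intronFraction(g2), 0.8)
  g3 <- geneModels("g3", "chr1", 0, 100, "+")
  expect_error(intronFraction(g3), "no exons")
  # random layouts vs per-bp labeling oracle
  set.seed(5)
  for (r in 1:5) {
    L <- 1000L
    es <- sort(sample(0:980, 4))
    es <- es[c(TRUE, diff(es) > 20)]  # enforce separation
    ee <- es + sample(5:15, length(es), TRUE)
    g <- geneModels("gx", "chr1", 0, L, "+", exons = list(cbind(es, ee)))
    bp <- logical(L)
    for (k in seq_along(es)) bp[(es[k] + 1):ee[k]] <- TRUE
    expect_equal(intronFraction(g), 1 - mean(bp))
  }
})

test_that("threshold peak calling merges, filters and measures runs", {
  z <- SignalTrack(list(c1 = rep(0, 100)), step = 100L)
  expect_length(callPeaksFromSignal(z, 1), 0L)
  pulse <- rep(0, 100); pulse[21:70] <- 4
  tr <- SignalTrack(list(c1 = pulse), step = 100L)
  pk <- callPeaksFromSignal(tr, 1)
  expect_equal(width(pk), 5000L)
  expect_equal(pk$height, 4)
  # two pulses 100 bp apart merge under merge_gap 200
  v <- rep(0, 50); v[11:20] <- 2; v[22:30] <- 3  # gap of 1 bin = 100 bp
  tr2 <- SignalTrack(list(c1 = v), step = 100L)
  expect_length(callPeaksFromSignal(tr2, 1, merge_gap = 200), 1L)
  expect_length(callPeaksFromSignal(tr2, 1, merge_gap = 0), 2L)
  # min_width drops short runs
  expect_length(callPeaksFromSignal(tr2, 1, min_width = 950), 1L)
})
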