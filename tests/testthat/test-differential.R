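test_that("identical conditions yield no pairwise calls", {
  set.seed(61)
  w <- stats::setNames(c(rep(0, 500), rexp(500, 1 / 2e4)),
    sprintf("g%04d", 1:1000))
  calls <- pairwiseDifferential(w, w)
  expect_true(all(calls$class == "unchanged"))
})

test_that("a dominant single shrink is called shortened", {
  set.seed(62)
  ids <- sprintf("g%04d", 1:500)
  ref <- stats::setNames(abs(rnorm(500, 0, 500)), ids)
  ref["g0001"] <- 2e5
  test <- ref
  test["g0001"] <- 2e4
  calls <- pairwiseDifferential(ref, test)
  expect_equal(calls$class[calls$gene_id == "g0001"], "shortened")
  expect_lte(sum(calls$class == "shortened"), 3)
})

test_that("swapping reference and test exchanges the two call classes", {
  set.seed(63)
  ids <- sprintf("g%04d", 1:800)
  ref <- stats::setNames(rexp(800, 1 / 3e4), ids)
  test <- ref
  test[1:25] <- test[1:25] * 0.05
  test[26:35] <- test[26:35] * 4
  a <- pairwiseDifferential(ref, test)
  b <- pairwiseDifferential(test, ref)
  expect_equal(a$gene_id[a$class == "shortened"],
    b$gene_id[b$class == "lengthened"])
  expect_equal(a$gene_id[a$class == "lengthened"],
    b$gene_id[b$class == "shortened"])
})

test_that("planted 100 kb shortenings are recovered over 5 kb noise", {
  set.seed(64)
  ids <- sprintf("g%04d", 1:2000)
  ref <- stats::setNames(rexp(2000, 1 / 3e4), ids)
  test <- ref + rnorm(2000, 0, 5000)
  test <- pmax(test, 0)
  planted <- sample(ids, 40)
  test[planted] <- pmax(ref[planted] - 1e5, 0)
  ref[planted] <- ref[planted] + 1e5  # ensure the 100 kb drop exists
  test[planted] <- ref[planted] - 1e5
  calls <- pairwiseDifferential(ref, test)
  called <- calls$gene_id[calls$class == "shortened"]
  expect_gte(length(intersect(called, planted)) / 40, 0.9)
  expect_lte(length(setdiff(called, planted)), 5)
})

test_that("the per-class cap keeps only the most extreme calls", {
  set.seed(65)
  ids <- sprintf("g%04d", 1:1000)
  ref <- stats::setNames(rep(2e5, 1000), ids)
  test <- ref
  test[1:100] <- ref[1:100] - seq(5e4, 1.5e5, length.out = 100)
  capped <- pairwiseDifferential(ref, test, n_top = 20)
  expect_lte(sum(capped$class == "shortened"), 20)
  sh <- capped$gene_id[capped$class == "shortened"]
  expect_true(all(sh %in% ids[81:100]))  # the 20 largest drops
  uncapped <- pairwiseDifferential(ref, test, cap = FALSE)
  expect_gte(sum(uncapped$class == "shortened"),
    sum(capped$class == "shortened"))
})

cohortFixture <- function(n_genes = 60, seed = 71) {
  set.seed(seed)
  ids <- sprintf("g%03d", seq_len(n_genes))
  wN <- matrix(rep(c(rep(8e4, 10), rep(0, n_genes - 10)), 4), ncol = 4,
    dimnames = list(ids, sprintf("n%d", 1:4)))
  wC <- wN[, 1:3]
  colnames(wC) <- sprintf("c%d", 1:3)
  list(ids = ids, wN = wN, wC = wC)
}

asMatrixWm <- function(w, labels, cutoff = 1e4) {
  st <- lapply(seq_len(ncol(w)), function(j)
    data.frame(gene_id = rownames(w), width_sum = w[, j]))
  names(st) <- colnames(w)
  buildWidthMatrix(st, bgrd_rule = list(cutoff = cutoff), labels = labels)
}

test_that("cohort thresholds are strict and need both criteria", {
  fx <- cohortFixture()
  # gene g001: width drop of exactly 5000 and conservation drop 1
  wC <- fx$wC
  wC["g001", ] <- 8e4 - 5000
  x <- asMatrixWm(cbind(fx$wN, wC),
    c(stats::setNames(rep("normal", 4), colnames(fx$wN)),
      stats::setNames(rep("cancer", 3), colnames(wC))), cutoff = 7.6e4)
  calls <- cohortDifferential(x)
  expect_equal(calls$class[calls$gene_id == "g001"], "unchanged")
  # a full collapse passes both criteria
  wC2 <- fx$wC
  wC2["g002", ] <- 0
  x2 <- asMatrixWm(cbind(fx$wN, wC2),
    c(stats::setNames(rep("normal", 4), colnames(fx$wN)),
      stats::setNames(rep("cancer", 3), colnames(wC2))), cutoff = 1e4)
  calls2 <- cohortDifferential(x2)
  expect_equal(calls2$class[calls2$gene_id == "g002"], "shortened")
  expect_equal(sum(calls2$class != "unchanged"), 1L)
  # a missing label class is an error
  x3 <- asMatrixWm(fx$wN,
    stats::setNames(rep("normal", 4), colnames(fx$wN)))
  expect_error(cohortDifferential(x3), "both normal and cancer")
})

test_that("label shuffles on an exchangeable null give ~zero calls", {
  set.seed(72)
  ids <- sprintf("g%03d", 1:100)
  # all samples drawn iid from one distribution; domains fully stable
  w <- matrix(rep(c(rep(6e4, 20), rep(0, 80)), 9), ncol = 9,
    dimnames = list(ids, sprintf("s%d", 1:9)))
  w <- w + matrix(runif(900, 0, 500), ncol = 9)
  x <- asMatrixWm(w, stats::setNames(
    c(rep("normal", 5), rep("cancer", 4)), colnames(w)), cutoff = 3e4)
  real <- cohortDifferential(x)
  expect_equal(sum(real$class != "unchanged"), 0L)
  mn <- mockShuffle(x, n_reps = 200, seed = 5)
  expect_lt(mn@mean_shortened, 0.5)
  expect_lt(mn@mean_lengthened, 0.5)
})

test_that("mock shuffle summaries are bit-identical under a fixed seed", {
  fx <- cohortFixture()
  wC <- fx$wC; wC["g003", ] <- 0
  x <- asMatrixWm(cbind(fx$wN, wC),
    c(stats::setNames(rep("normal", 4), colnames(fx$wN)),
      stats::setNames(rep("cancer", 3), colnames(wC))), cutoff = 1e4)
  a <- mockShuffle(x, n_reps = 50, seed = 9)
  b <- mockShuffle(x, n_reps = 50, seed = 9)
  expect_identical(a@counts, b@counts)
  expect_identical(a@mean_shortened, b@mean_shortened)
})

test_that("differential enrichment scores classes against the universe", {
  uni <- sprintf("g%04d", 1:2000)
  categ <- uni[1:200]
  calls <- data.frame(gene_id = uni,
    class = c(rep("shortened", 100), rep("unchanged", 1900)))
  # shortened set drawn entirely from the category: maximal enrichment
  res <- differentialEnrichment(calls, categ, uni)
  expect_equal(res$shortened$observed, 100)
  expect_equal(res$shortened$fold, 10)
  expect_lt(res$shortened$p, 1e-50)
  # random class assignment is near fold 1
  set.seed(73)
  calls2 <- data.frame(gene_id = uni,
    class = sample(c(rep("shortened", 400), rep("unchanged", 1600))))
  res2 <- differentialEnrichment(calls2, categ, uni)
  expect_lt(abs(res2$shortened$fold - 1), 0.35)
  # empty class is skipped with a note, not an error
  expect_message(differentialEnrichment(calls, categ, uni), "empty")
})
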