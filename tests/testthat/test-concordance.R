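test_that("cohort means reduce exactly and ignore sample order", {
  qm <- rand_qm(20, 10, seed = 51, scale = "log2")
  meta <- two_cohort_meta(qm$sample_ids, 1)
  expect_equal(cohort_means(qm, meta, "A"), qm$values[, 1])
  meta2 <- two_cohort_meta(qm$sample_ids, 4)
  expect_equal(cohort_means(qm, meta2, "B"),
               apply(qm$values[, 5:10], 1, mean))
  perm <- sample(nrow(meta2))
  expect_equal(cohort_means(qm, meta2[perm, ], "B"),
               cohort_means(qm, meta2, "B"))
  expect_error(cohort_means(qm, meta2, "Z"), "absent")
})

test_that("pearson_between is the textbook sample correlation", {
  m <- rnorm(50, 20, 2)
  expect_equal(pearson_between(m, m), 1)
  expect_equal(pearson_between(m, -m + 2 * mean(m)), -1)
  set.seed(52)
  mB <- m + rnorm(50, 0, 0.5)
  num <- sum((m - mean(m)) * (mB - mean(mB)))
  den <- sqrt(sum((m - mean(m))^2) * sum((mB - mean(mB))^2))
  expect_equal(pearson_between(m, mB), num / den, tolerance = 1e-12)
  expect_error(pearson_between(rep(1, 10), mB[1:10]), "zero variance")
})

test_that("ICC(2,1) matches the two-way ANOVA oracle and penalizes offsets", {
  set.seed(53)
  mA <- rnorm(10, 20, 2)
  expect_equal(icc_between(mA, mA), 1)
  # constant offset: absolute agreement drops below 1, value from the oracle
  off <- icc_between(mA, mA + 1)
  expect_lt(off, 1)
  expect_equal(off, icc21_oracle(mA, mA + 1), tolerance = 1e-10)
  # a 6 x 2 worked table against the same oracle
  a6 <- c(9, 6, 8, 7, 10, 6); b6 <- c(2, 1, 4, 1, 5, 2)
  expect_equal(icc_between(a6, b6), icc21_oracle(a6, b6), tolerance = 1e-10)
  mB <- mA + rnorm(10, 0, 0.5)
  expect_equal(icc_between(mA, mB), icc21_oracle(mA, mB), tolerance = 1e-10)
  expect_equal(icc_between(rep(3, 5), rep(3, 5)), 1)
})

test_that("percent similarity has its closed form and clamps", {
  m <- c(21, 20, 18)
  expect_equal(percent_similarity(m, m), rep(100, 3))
  expect_equal(percent_similarity(21, 19), 90)
  expect_equal(percent_similarity(c(30, 1), c(-10, 1))[1], 0)  # clamped
  expect_warning(percent_similarity(1, -1), "non-positive")
})

test_that("Bland-Altman statistics match the hand computation on d = 1..5", {
  mB <- rep(10, 5)
  ba <- bland_altman(mB + 1:5, mB)
  expect_equal(ba$d, 1:5 + 0)
  expect_equal(ba$mean_d, 3)
  expect_equal(ba$sd_d, sqrt(2.5))
  expect_equal(ba$loa_low, 3 - 1.96 * sqrt(2.5))
  expect_equal(ba$loa_high, 3 + 1.96 * sqrt(2.5))
  expect_equal(mean(ba$z), 0, tolerance = 1e-12)
  expect_equal(sd(ba$z), 1, tolerance = 1e-12)
  # identical vectors: degenerate rule
  ba0 <- bland_altman(mB, mB)
  expect_equal(ba0$z, rep(0, 5))
  expect_false(any(ba0$flag))
})

test_that("the GSI self-comparison is exactly 1 and is symmetric in cohorts", {
  qm <- rand_qm(50, 8, seed = 55, scale = "log2")
  v <- cbind(qm$values[, 1:4], qm$values[, 1:4])
  colnames(v) <- sprintf("s%02d", 1:8)
  dup <- quant_matrix(v, scale = "log2")
  meta <- two_cohort_meta(dup$sample_ids, 4)
  res <- compute_gsi(dup, meta, "A", "B")
  expect_identical(res$global_gsi, 1)
  expect_true(all(res$per_protein$gsi == 1))
  expect_true(all(res$per_protein$category == "very_high"))

  # swapping cohorts leaves every per-protein gsi unchanged
  qn <- rand_qm(40, 10, seed = 56, scale = "log2")
  meta2 <- two_cohort_meta(qn$sample_ids, 5)
  ab <- compute_gsi(qn, meta2, "A", "B")
  ba <- compute_gsi(qn, meta2, "B", "A")
  expect_equal(ab$per_protein$gsi, ba$per_protein$gsi, tolerance = 1e-12)
  expect_equal(ab$per_protein$d, -ba$per_protein$d)
  expect_equal(ab$pearson, ba$pearson)
  expect_equal(ab$icc, ba$icc)
})

test_that("per-protein GSI reproduces a from-scratch spreadsheet oracle", {
  set.seed(57)
  p <- 5
  vA <- matrix(rnorm(p * 2, 20, 1), p, 2)
  vB <- vA + matrix(rnorm(p * 2, 0.2, 0.3), p, 2)
  v <- cbind(vA, vB)
  dimnames(v) <- list(paste0("P", 1:p), paste0("s", 1:4))
  qm <- quant_matrix(v, scale = "log2")
  meta <- two_cohort_meta(qm$sample_ids, 2)
  res <- compute_gsi(qm, meta, "A", "B")

  # oracle: everything from sums, no package calls
  mA <- (v[, 1] + v[, 2]) / 2; mB <- (v[, 3] + v[, 4]) / 2
  r_num <- sum((mA - mean(mA)) * (mB - mean(mB)))
  r <- r_num / sqrt(sum((mA - mean(mA))^2) * sum((mB - mean(mB))^2))
  x <- cbind(mA, mB); grand <- mean(x)
  msr <- 2 * sum((rowMeans(x) - grand)^2) / (p - 1)
  msc <- p * sum((colMeans(x) - grand)^2)
  sse <- sum((x - grand)^2) - 2 * sum((rowMeans(x) - grand)^2) -
    p * sum((colMeans(x) - grand)^2)
  mse <- sse / (p - 1)
  icc <- (msr - mse) / (msr + mse + (2 / p) * (msc - mse))
  d <- mA - mB
  z <- (d - mean(d)) / sqrt(sum((d - mean(d))^2) / (p - 1))
  pm <- (mA + mB) / 2
  psim <- pmin(pmax(100 * (1 - abs(d) / pm), 0), 100)
  pdiff <- 100 * abs(d) / pm
  gsi <- 0.25 * (r + 1) / 2 + 0.25 * max(0, icc) + 0.20 * psim / 100 +
    0.15 * (1 - pmin(pdiff, 100) / 100) +
    0.15 * pmax(0, 1 - abs(z) / 1.96)
  expect_equal(res$per_protein$gsi, unname(gsi), tolerance = 1e-9)
  expect_equal(res$global_gsi, mean(gsi), tolerance = 1e-9)
})

test_that("default GSI weights are 25/25/20/15/15 and must sum to one", {
  w <- gsi_weights()
  expect_identical(c(w$w_pearson, w$w_icc, w$w_psim, w$w_pdiff, w$w_z),
                   c(0.25, 0.25, 0.20, 0.15, 0.15))
  expect_identical(w$z_crit, 1.96)
  expect_error(gsi_weights(w_pearson = 0.5), "sum to 1")
})

test_that("similarity categories bin at 0.90/0.75/0.50", {
  counts <- classify_similarity(c(0.95, 0.80, 0.60, 0.40))
  expect_equal(unname(counts[c("very_high", "high", "moderate", "low")]),
               rep(1L, 4))
  all_one <- classify_similarity(rep(1, 7))
  expect_equal(unname(all_one["very_high"]), 7L)
  expect_equal(attr(all_one, "majority"), "very_high")
})

test_that("every GSI component stays inside [0, 1] under heavy disagreement", {
  set.seed(58)
  qm <- rand_qm(100, 12, seed = 58, scale = "log2")
  v <- qm$values
  v[, 7:12] <- v[, 7:12] + matrix(rnorm(600, 0, 5), 100, 6)
  noisy <- quant_matrix(v, scale = "log2")
  meta <- two_cohort_meta(noisy$sample_ids, 6)
  res <- compute_gsi(noisy, meta, "A", "B")
  comp <- as.matrix(res$per_protein[, c("c1", "c2", "c3", "c4", "c5", "gsi")])
  expect_true(all(comp >= 0 & comp <= 1))
})
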