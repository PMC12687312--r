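test_that("valid-fraction rules keep exactly what the fraction oracle keeps", {
  # cohort A: 8 samples, cohort B: 58 samples; random masks
  set.seed(21)
  p <- 40; nA <- 8; nB <- 58
  vals <- matrix(2^rnorm(p * (nA + nB), 20, 1), p,
                 dimnames = list(sprintf("P%03d", 1:p),
                                 sprintf("s%02d", 1:(nA + nB))))
  mask <- matrix(runif(length(vals)) < 0.5, p, nA + nB)
  mask[1, ] <- c(rep(c(TRUE, FALSE), c(3, 5)),      # 3/8 = 0.375 in A
                 rep(c(TRUE, FALSE), c(21, 37)))    # 21/58 = 0.362 in B
  mask[2, ] <- FALSE                                 # never observed
  mask[3, ] <- c(rep(TRUE, 8), rep(FALSE, 58))       # 100% in A only
  v <- vals; v[!mask] <- NA
  qm <- quant_matrix(v, mask = mask)
  meta <- two_cohort_meta(qm$sample_ids, nA, groupA = "NHA", groupB = "ACC")

  fA <- rowSums(mask[, 1:nA]) / nA
  fB <- rowSums(mask[, nA + 1:nB]) / nB
  kept_cohort <- filter_by_valid_fraction(qm, meta,
                                          filter_rule("each_cohort"))
  expect_identical(kept_cohort$protein_ids,
                   qm$protein_ids[fA >= 0.35 & fB >= 0.35])
  # groups coincide with cohorts in this design, so the group oracle is fA/fB
  kept_group <- filter_by_valid_fraction(qm, meta, filter_rule("any_group"))
  expect_identical(kept_group$protein_ids,
                   qm$protein_ids[fA >= 0.60 | fB >= 0.60])

  # the enumerated edge cases
  expect_true("P001" %in% kept_cohort$protein_ids)   # 0.375 and 0.362
  expect_false("P002" %in% kept_cohort$protein_ids)  # all missing
  expect_false("P002" %in% kept_group$protein_ids)
  expect_true("P003" %in% kept_group$protein_ids)    # 100% in one group
  # filtering never grows the matrix and preserves values
  expect_lte(nrow(kept_cohort$values), p)
  expect_identical(kept_cohort$values["P001", ], qm$values["P001", ])
})

test_that("log2 transform is exact, guarded, and invertible", {
  m <- matrix(c(8, 1, 2, 1024), 2, 2,
              dimnames = list(c("P1", "P2"), c("s1", "s2")))
  qm <- log2_transform(quant_matrix(m))
  expect_equal(qm$values[1, 1], 3)
  expect_equal(qm$values[2, 1], 0)
  expect_equal(qm$scale, "log2")
  expect_error(log2_transform(qm), "already")

  r <- rand_qm(30, 6, seed = 5, miss_rate = 0.2)
  lt <- log2_transform(r)
  expect_equal(2^lt$values[lt$mask], r$values[r$mask])
  expect_identical(lt$mask, r$mask)
})

test_that("quantile normalization matches a rank/mean-quantile oracle on the 4x3 fixture", {
  x <- matrix(c(5, 2, 3, 4, 4, 1, 4, 2, 3, 4, 6, 8), 4, 3,
              dimnames = list(paste0("P", 1:4), paste0("s", 1:3)))
  qm <- quantile_normalize(quant_matrix(x, scale = "log2"))
  # oracle: reference = mean of column order statistics; assignment by
  # average rank through stats::quantile on the sorted reference
  ref <- rowMeans(apply(x, 2, sort))
  grid <- seq(0, 1, length.out = nrow(x))
  expected <- x
  for (j in 1:3) {
    pos <- (rank(x[, j], ties.method = "average") - 1) / (nrow(x) - 1)
    expected[, j] <- unname(stats::quantile(ref, pos, type = 7))
  }
  expect_equal(qm$values, expected, tolerance = 1e-12)
  # tie-free columns acquire exactly the reference multiset
  for (j in c(1, 3)) expect_equal(sort(unname(qm$values[, j])), unname(ref))
})

test_that("quantile normalization agrees with limma and is idempotent on complete data", {
  skip_if_not_installed("limma")
  set.seed(13)
  x <- matrix(sample(1:30, 80, replace = TRUE) + 10, 20, 4,
              dimnames = list(sprintf("P%02d", 1:20), paste0("s", 1:4)))
  qm <- quant_matrix(x * 1.0, scale = "log2")
  mine <- quantile_normalize(qm)
  expect_equal(mine$values,
               limma::normalizeQuantiles(x * 1.0, ties = TRUE),
               tolerance = 1e-12)
  # idempotence on a tie-free complete matrix
  y <- matrix(rnorm(80, 20, 2), 20, 4,
              dimnames = dimnames(x))
  once <- quantile_normalize(quant_matrix(y, scale = "log2"))
  twice <- quantile_normalize(once)
  expect_equal(twice$values, once$values, tolerance = 1e-9)
  # columns already identical are a fixed point
  same <- matrix(rep(c(3, 1, 2, 5), 3), 4, 3,
                 dimnames = list(paste0("P", 1:4), paste0("s", 1:3)))
  expect_equal(quantile_normalize(quant_matrix(same, scale = "log2"))$values,
               same)
})

test_that("with missing cells observed values interpolate the reference curve", {
  x <- matrix(c(1, 2, 3, 4, 5,
                2, 4, NA, 8, 10,
                1.5, NA, NA, 7, 9), 5, 3,
              dimnames = list(paste0("P", 1:5), paste0("s", 1:3)))
  qm <- quantile_normalize(quant_matrix(x, scale = "log2",
                                        mask = !is.na(x)))
  # oracle: explicit interpolation script
  n <- nrow(x); grid <- seq(0, 1, length.out = n)
  curves <- sapply(1:3, function(j) {
    o <- sort(x[!is.na(x[, j]), j])
    stats::approx(seq(0, 1, length.out = length(o)), o, xout = grid)$y
  })
  ref <- rowMeans(curves)
  for (j in 1:3) {
    obs <- which(!is.na(x[, j]))
    pos <- (rank(x[obs, j]) - 1) / (length(obs) - 1)
    expect_equal(qm$values[obs, j],
                 stats::approx(grid, ref, xout = pos)$y,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_identical(is.na(qm$values), is.na(x))
  # a column with fewer than two observed values is refused by name
  bad <- x; bad[2:5, 2] <- NA
  expect_error(quantile_normalize(quant_matrix(bad, scale = "log2",
                                               mask = !is.na(bad))), "s2")
})

test_that("pca_impute recovers a rank-1 completion and never touches observed cells", {
  set.seed(31)
  a <- runif(8, 1, 2); b <- runif(6, 10, 20)
  full <- outer(a, b)
  dimnames(full) <- list(paste0("P", 1:8), paste0("s", 1:6))
  holed <- full; holed[3, 4] <- NA
  qm <- quant_matrix(holed, scale = "log2", mask = !is.na(holed))
  imp <- pca_impute(qm, n_components = 1, tol = 1e-9, max_iter = 2000)
  expect_lt(abs(imp$values[3, 4] - full[3, 4]), 1e-6)
  expect_identical(imp$values[qm$mask], qm$values[qm$mask])
  expect_true(all(imp$mask))
  expect_identical(which(imp$imputed), which(is.na(holed)))

  # complete input is a fixed point
  qc <- quant_matrix(full, scale = "log2")
  expect_identical(pca_impute(qc)$values, full)

  # observed cells bit-identical on a noisy fixture too
  r <- rand_qm(40, 8, seed = 17, miss_rate = 0.15, scale = "log2")
  ri <- pca_impute(r, max_iter = 5000)
  expect_identical(ri$values[r$mask], r$values[r$mask])
})

test_that("pca_impute guards degenerate inputs", {
  x <- matrix(c(NA, 1, NA, 2, NA, 3), 2, 3,
              dimnames = list(c("P1", "P2"), paste0("s", 1:3)))
  qm <- quant_matrix(x, scale = "log2", mask = !is.na(x))
  expect_error(pca_impute(qm, n_components = 1), "P1")
  expect_error(pca_impute(rand_qm(5, 4, scale = "log2"), n_components = 4),
               "n_components")
})

test_that("cohort centering removes exactly the scalar batch shift", {
  qm <- rand_qm(30, 10, seed = 8, scale = "log2")
  meta <- two_cohort_meta(qm$sample_ids, 4)
  # cohorts already share a grand mean: centering is a no-op
  v <- qm$values
  v[, 5:10] <- v[, 5:10] - mean(v[, 5:10]) + mean(v[, 1:4])
  bal <- quant_matrix(v, scale = "log2")
  expect_equal(center_cohorts(bal, meta)$values, bal$values)

  # cohort B equals cohort A plus a constant: per-protein differences vanish
  vA <- qm$values[, 1:4]
  sv <- cbind(vA, vA + 2.5)
  colnames(sv) <- sprintf("s%02d", 1:8)
  shifted <- quant_matrix(sv, scale = "log2")
  meta8 <- two_cohort_meta(colnames(sv), 4)
  cen <- center_cohorts(shifted, meta8)
  expect_equal(rowMeans(cen$values[, 5:8]) - rowMeans(cen$values[, 1:4]),
               rep(0, 30), tolerance = 1e-12, ignore_attr = TRUE)

  # simulated batch shift of 1.5 leaves residual shift below 0.05
  cfg <- sim_config(n_proteins = 400,
                    design = data.frame(cohort = c("A", "B"), group = "ACC",
                                        n = c(8L, 12L)),
                    dep_fraction = 0, batch_shift_log2 = 1.5, seed = 9)
  sim <- simulate_cohorts(cfg)
  lqm <- center_cohorts(log2_transform(sim$matrix), sim$metadata)
  resid <- abs(mean(cohort_means(lqm, sim$metadata, "B")) -
               mean(cohort_means(lqm, sim$metadata, "A")))
  expect_lt(resid, 0.05)
})

test_that("pca_scores match an eigendecomposition oracle up to sign", {
  qm <- rand_qm(10, 6, seed = 14, scale = "log2")
  sc <- pca_scores(qm, n_components = 3)
  xc <- qm$values - rowMeans(qm$values)
  eig <- eigen(crossprod(xc), symmetric = TRUE)
  for (i in 1:3) {
    oracle <- eig$vectors[, i] * sqrt(eig$values[i])
    expect_equal(min(max(abs(sc[[paste0("PC", i)]] - oracle)),
                     max(abs(sc[[paste0("PC", i)]] + oracle))),
                 0, tolerance = 1e-8)
  }
  # total score variance cannot exceed centered-data variance
  expect_lte(sum(as.matrix(sc[, -1])^2), sum(xc^2) + 1e-8)

  # duplicated samples receive identical scores
  v <- qm$values; v[, 2] <- v[, 1]
  dup <- quant_matrix(v, scale = "log2")
  sd2 <- pca_scores(dup)
  expect_equal(unlist(sd2[1, -1]), unlist(sd2[2, -1]), tolerance = 1e-10)
  # incomplete matrices are rejected
  holey <- rand_qm(10, 6, seed = 15, miss_rate = 0.2, scale = "log2")
  expect_error(pca_scores(holey), "impute")
})
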