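# Small in-code fixture builders shared across test files.

# Random raw-scale QuantMatrix with optional MCAR missingness.
rand_qm <- function(p, n, seed = 1, miss_rate = 0, scale = "raw") {
  set.seed(seed)
  x <- matrix(2^rnorm(p * n, 20, 2), p, n,
              dimnames = list(sprintf("P%03d", seq_len(p)),
                              sprintf("s%02d", seq_len(n))))
  if (miss_rate > 0) {
    x[matrix(runif(p * n) < miss_rate, p, n)] <- NA
    # keep every row/column partly observed
    for (i in which(rowSums(!is.na(x)) == 0)) x[i, 1] <- 2^20
    for (j in which(colSums(!is.na(x)) == 0)) x[1, j] <- 2^20
  }
  if (scale == "log2") {
    x[!is.na(x)] <- log2(x[!is.na(x)])
  }
  quant_matrix(x, scale = scale)
}

# Metadata for a matrix whose samples split into cohorts/groups by count.
meta_for <- function(sample_ids, cohort, group) {
  data.frame(sample_id = sample_ids,
             cohort = rep_len(cohort, length(sample_ids)),
             group = rep_len(group, length(sample_ids)),
             stringsAsFactors = FALSE)
}

# Two-cohort metadata: first nA samples cohort A, rest cohort B.
two_cohort_meta <- function(sample_ids, nA, groupA = "ACC", groupB = "ACC") {
  n <- length(sample_ids)
  data.frame(sample_id = sample_ids,
             cohort = rep(c("A", "B"), c(nA, n - nA)),
             group = c(rep_len(groupA, nA), rep_len(groupB, n - nA)),
             stringsAsFactors = FALSE)
}

# Brute-force BH step-up: q_(i) = min_{j >= i} m p_(j) / j, explicit loops.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Two-way ANOVA mean squares via stats::aov, for the ICC oracle.
icc21_oracle <- function(mA, mB) {
  n <- length(mA)
  long <- data.frame(y = c(mA, mB),
                     subj = factor(rep(seq_len(n), 2)),
                     rater = factor(rep(c("A", "B"), each = n)))
  tab <- summary(stats::aov(y ~ subj + rater, data = long))[[1]]
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
}
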