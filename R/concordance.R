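#' Weights of the Global Similarity Index
#'
#' The GSI is a weighted average of five agreement measures between two
#' cohorts: Pearson correlation (25%), intraclass correlation coefficient
#' (25%), percent similarity (20%), Bland-Altman percent difference (15%)
#' and standardized Z-score (15%). `z_crit = 1.96` is the significance
#' threshold of the standardized Bland-Altman Z-scores (and the point at
#' which the Z component of the GSI reaches zero).
#'
#' @param w_pearson,w_icc,w_psim,w_pdiff,w_z Component weights; must sum
#'   to 1.
#' @param z_crit Z-score threshold.
#' @return A `gsi_weights` list.
#' @export
gsi_weights <- function(w_pearson = 0.25, w_icc = 0.25, w_psim = 0.20,
                        w_pdiff = 0.15, w_z = 0.15, z_crit = 1.96) {
  w <- c(w_pearson, w_icc, w_psim, w_pdiff, w_z)
  if (abs(sum(w) - 1) > 1e-12) stop("GSI weights must sum to 1")
  structure(list(w_pearson = w_pearson, w_icc = w_icc, w_psim = w_psim,
                 w_pdiff = w_pdiff, w_z = w_z, z_crit = z_crit),
            class = "gsi_weights")
}

#' Per-protein means of one cohort's samples
#' @param qm A complete log2-scale [quant_matrix()].
#' @param meta Sample metadata.
#' @param cohort Cohort label.
#' @return Named numeric vector of per-protein means.
#' @export
cohort_means <- function(qm, meta, cohort) {
  validate_quant_matrix(qm)
  meta <- match_metadata(qm, meta)
  cols <- which(meta$cohort == cohort)
  if (!length(cols)) stop("cohort absent from metadata: ", cohort)
  rowMeans(qm$values[, cols, drop = FALSE])
}

#' Pearson correlation between cohort mean vectors
#' @param mA,mB Per-protein mean vectors of the two cohorts.
#' @return The sample Pearson correlation.
#' @export
pearson_between <- function(mA, mB) {
  stopifnot(length(mA) == length(mB))
  if (length(mA) < 3L) stop("need at least 3 proteins")
  if (stats::sd(mA) == 0 || stats::sd(mB) == 0) {
    stop("zero variance in a cohort mean vector")
  }
  stats::cor(mA, mB)
}

#' Intraclass correlation coefficient ICC(2,1) between cohorts
#'
#' Two-way random effects, absolute agreement, single rater: proteins are
#' the subjects (n rows) and the two cohorts the raters (k = 2 columns).
#' From the two-way ANOVA mean squares of the n x 2 matrix,
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`. Absolute
#' agreement means a systematic offset between cohorts lowers the ICC,
#' which is the behaviour wanted of a reproducibility score. When all
#' values are identical (degenerate ANOVA) the ICC is defined as 1.
#'
#' @param mA,mB Per-protein mean vectors of the two cohorts.
#' @return The ICC(2,1) estimate.
#' @export
icc_between <- function(mA, mB) {
  stopifnot(length(mA) == length(mB))
  n <- length(mA)
  if (n < 3L) stop("need at least 3 proteins")
  x <- cbind(mA, mB)
  k <- 2L
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((x - grand)^2) - k * sum((row_m - grand)^2) -
    n * sum((col_m - grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom == 0) return(1)  # all values identical
  (msr - mse) / denom
}

#' Per-protein percent similarity between cohorts
#'
#' `psim_g = 100 * (1 - |mA_g - mB_g| / ((mA_g + mB_g) / 2))`, clamped to
#' `[0, 100]`. Computed on log2-scale means, which are far from zero for
#' intensity data; a non-positive pair mean yields 0 with a warning.
#'
#' @param mA,mB Per-protein mean vectors.
#' @return Percent similarity per protein, in `[0, 100]`.
#' @export
percent_similarity <- function(mA, mB) {
  stopifnot(length(mA) == length(mB))
  pair_mean <- (mA + mB) / 2
  psim <- 100 * (1 - abs(mA - mB) / pair_mean)
  bad <- pair_mean <= 0
  if (any(bad)) {
    warning(sum(bad), " protein(s) with non-positive pair mean; psim set to 0")
    psim[bad] <- 0
  }
  pmin(pmax(psim, 0), 100)
}

#' Bland-Altman agreement analysis between cohorts
#'
#' Per-protein differences `d_g = mA_g - mB_g`, their mean (bias),
#' standard deviation, limits of agreement `mean_d +/- 1.96 sd_d`, and
#' standardized Z-scores `z_g = (d_g - mean_d) / sd_d` flagged at
#' `|z| > z_crit`. When `sd_d = 0` (identical vectors) every `z_g` is
#' defined as 0 and nothing is flagged, so a self-comparison is
#' well-behaved.
#'
#' @param mA,mB Per-protein mean vectors (length at least 3).
#' @param z_crit Flagging threshold (default 1.96).
#' @return A `BlandAltmanResult` list: `d`, `mean_d`, `sd_d`, `loa_low`,
#'   `loa_high`, `z`, `flag`, `z_crit`.
#' @export
bland_altman <- function(mA, mB, z_crit = 1.96) {
  stopifnot(length(mA) == length(mB))
  if (length(mA) < 3L) stop("need at least 3 proteins")
  d <- mA - mB
  mean_d <- mean(d)
  sd_d <- stats::sd(d)
  z <- if (sd_d > 0) (d - mean_d) / sd_d else rep(0, length(d))
  structure(list(d = d, mean_d = mean_d, sd_d = sd_d,
                 loa_low = mean_d - 1.96 * sd_d,
                 loa_high = mean_d + 1.96 * sd_d,
                 z = z, flag = abs(z) > z_crit, z_crit = z_crit),
            class = "BlandAltmanResult")
}

#' Global Similarity Index between two cohorts
#'
#' Scores cross-cohort agreement on `[0, 1]` per protein and globally.
#' Two components are global statistics on the cohort mean vectors and are
#' broadcast to every protein (a per-protein Pearson or ICC across two
#' points would be undefined): `c1 = (pearson + 1) / 2` and
#' `c2 = max(0, icc)`. Three are per-protein: `c3 = psim / 100`,
#' `c4 = 1 - min(pdiff, 100) / 100` with
#' `pdiff_g = 100 |d_g| / ((mA_g + mB_g)/2)` the Bland-Altman percent
#' difference, and `c5 = max(0, 1 - |z_g| / z_crit)`, a linear penalty
#' vanishing at the Z significance threshold. Then
#' `gsi_g = 0.25 c1 + 0.25 c2 + 0.20 c3_g + 0.15 c4_g + 0.15 c5_g` under
#' the default [gsi_weights()], and the global GSI is the mean over
#' proteins. Categories: very_high (gsi >= 0.90), high (>= 0.75),
#' moderate (>= 0.50), low otherwise.
#'
#' @param qm A complete log2-scale [quant_matrix()] (preprocessing done).
#' @param meta Sample metadata.
#' @param cohortA,cohortB Cohort labels to compare.
#' @param weights A [gsi_weights()].
#' @return A `ConcordanceResult` list: `per_protein` data.frame
#'   (`protein_id`, `mA`, `mB`, `d`, `z`, `flag`, `psim`, `pdiff`,
#'   `c1`..`c5`, `gsi`, `category`), `pearson`, `icc`, `bland_altman`,
#'   `global_gsi`, `global_mean_psim`, `category_counts`, `weights`.
#' @export
#' @examples
#' sim <- simulate_cohorts(sim_config(n_proteins = 100,
#'   design = data.frame(cohort = c("A", "B"), group = "ACC",
#'                       n = c(4L, 4L)),
#'   batch_shift_log2 = 0, seed = 11))
#' qm <- log2_transform(sim$matrix)
#' res <- compute_gsi(qm, sim$metadata, "A", "B")
#' res$global_gsi
compute_gsi <- function(qm, meta, cohortA, cohortB,
                        weights = gsi_weights()) {
  mA <- cohort_means(qm, meta, cohortA)
  mB <- cohort_means(qm, meta, cohortB)
  pearson <- pearson_between(mA, mB)
  icc <- icc_between(mA, mB)
  ba <- bland_altman(mA, mB, z_crit = weights$z_crit)
  psim <- percent_similarity(mA, mB)
  pair_mean <- (mA + mB) / 2
  pdiff <- ifelse(pair_mean > 0, 100 * abs(ba$d) / pair_mean, 100)
  c1 <- (pearson + 1) / 2
  c2 <- max(0, icc)
  c3 <- psim / 100
  c4 <- 1 - pmin(pdiff, 100) / 100
  c5 <- pmax(0, 1 - abs(ba$z) / weights$z_crit)
  gsi <- weights$w_pearson * c1 + weights$w_icc * c2 +
    weights$w_psim * c3 + weights$w_pdiff * c4 + weights$w_z * c5
  category <- cut(gsi, breaks = c(-Inf, 0.50, 0.75, 0.90, Inf),
                  labels = c("low", "moderate", "high", "very_high"),
                  right = FALSE)
  per_protein <- data.frame(
    protein_id = qm$protein_ids, mA = mA, mB = mB, d = ba$d, z = ba$z,
    flag = ba$flag, psim = psim, pdiff = pdiff, c1 = c1, c2 = c2,
    c3 = c3, c4 = c4, c5 = c5, gsi = gsi,
    category = as.character(category),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_protein = per_protein, pearson = pearson, icc = icc,
                 bland_altman = ba, global_gsi = mean(gsi),
                 global_mean_psim = mean(psim),
                 category_counts = classify_similarity(gsi),
                 weights = weights),
            class = "ConcordanceResult")
}

#' Bin GSI scores into similarity categories
#'
#' Thresholds: very_high `gsi >= 0.90`, high `>= 0.75`, moderate
#' `>= 0.50`, low otherwise.
#'
#' @param gsi Vector of per-protein GSI scores in `[0, 1]`.
#' @return Named integer vector of counts (very_high, high, moderate,
#'   low), with the majority category as attribute `majority`.
#' @export
classify_similarity <- function(gsi) {
  stopifnot(all(gsi >= 0 & gsi <= 1))
  counts <- c(very_high = sum(gsi >= 0.90),
              high = sum(gsi >= 0.75 & gsi < 0.90),
              moderate = sum(gsi >= 0.50 & gsi < 0.75),
              low = sum(gsi < 0.50))
  attr(counts, "majority") <- names(counts)[which.max(counts)]
  counts
}

#' @export
print.ConcordanceResult <- function(x, ...) {
  cat(sprintf("ConcordanceResult: %d proteins\n", nrow(x$per_protein)))
  cat(sprintf("  Pearson %.4f | ICC(2,1) %.4f\n", x$pearson, x$icc))
  cat(sprintf("  Bland-Altman bias %.4g, LoA [%.4g, %.4g], %d flagged\n",
              x$bland_altman$mean_d, x$bland_altman$loa_low,
              x$bland_altman$loa_high, sum(x$bland_altman$flag)))
  cat(sprintf("  global GSI %.4f | mean percent similarity %.2f%%\n",
              x$global_gsi, x$global_mean_psim))
  cat("  categories:",
      paste(names(x$category_counts), x$category_counts, sep = "=",
            collapse = " "), "\n")
  invisible(x)
}
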