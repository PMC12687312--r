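#' Per-protein two-group linear fit
#'
#' For each protein computes the mean log2 difference between two groups
#' (`group2 - group1`), the pooled within-group variance and the residual
#' degrees of freedom `n1 + n2 - 2`.
#'
#' @param qm A complete log2-scale [quant_matrix()].
#' @param meta Sample metadata covering every sample.
#' @param group1,group2 Group labels to contrast; the reported effect is
#'   `mean(group2) - mean(group1)` (log2 fold-change of group2 over
#'   group1).
#' @return A data.frame with columns `protein_id`, `effect`, `s2`, `df`,
#'   and attributes `n1`, `n2`.
#' @export
fit_two_group <- function(qm, meta, group1, group2) {
  validate_quant_matrix(qm)
  if (!all(qm$mask)) stop("fit_two_group expects a complete matrix; impute first")
  meta <- match_metadata(qm, meta)
  i1 <- which(meta$group == group1)
  i2 <- which(meta$group == group2)
  if (!length(i1)) stop("group label absent from metadata: ", group1)
  if (!length(i2)) stop("group label absent from metadata: ", group2)
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  x1 <- qm$values[, i1, drop = FALSE]
  x2 <- qm$values[, i2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  df <- n1 + n2 - 2L
  out <- data.frame(protein_id = qm$protein_ids, effect = m2 - m1,
                    s2 = (ss1 + ss2) / df, df = df,
                    stringsAsFactors = FALSE)
  attr(out, "n1") <- n1
  attr(out, "n2") <- n2
  out
}

# Invert the trigamma function: solve trigamma(x) = y for x > 0.
# Newton iterations on the log scale with a bisection fallback; trigamma
# is strictly decreasing on (0, Inf) so the root is unique.
trigamma_inverse <- function(y, tol = 1e-8, max_iter = 100L) {
  vapply(y, function(yi) {
    if (yi <= 0) return(Inf)
    # bracket the root: trigamma(x) ~ 1/x for large x, ~ 1/x^2 near 0
    lo <- 0.5 / yi
    hi <- 0.5 + 1 / yi
    while (trigamma(lo) < yi) lo <- lo / 2
    while (trigamma(hi) > yi) hi <- hi * 2
    x <- 0.5 + 1 / yi
    for (i in seq_len(max_iter)) {
      f <- trigamma(x) - yi
      if (abs(f) < tol * yi) return(x)
      step <- f / psigamma(x, deriv = 2L)  # Newton (derivative is negative)
      x_new <- x - step
      if (!is.finite(x_new) || x_new <= lo || x_new >= hi) {
        x_new <- (lo + hi) / 2  # bisection fallback
      }
      if (trigamma(x_new) > yi) lo <- x_new else hi <- x_new
      if (abs(x_new - x) < tol * (1 + abs(x))) return(x_new)
      x <- x_new
    }
    x
  }, numeric(1))
}

#' Fit the variance prior for empirical-Bayes moderation
#'
#' Fits a scaled inverse-chi-square prior (`d0`, `s0_sq`) to the observed
#' per-protein variances by the classical method of moments on
#' log-variances: under the model `s2_g ~ s0_sq * F(df_g, d0)`, the
#' centered log-variances `e_g = log(s2_g) - digamma(df_g/2) +
#' log(df_g/2)` have mean `log(s0_sq) - digamma(d0/2) + log(d0/2)` and
#' excess variance `trigamma(d0/2)`, so `d0` is recovered by inverting the
#' trigamma function (Newton with bisection fallback, tolerance 1e-8) and
#' `s0_sq` from the mean. When the sample variance of the `e_g` does not
#' exceed the theoretical floor, `d0 = Inf` (no excess dispersion).
#'
#' @param s2 Vector of per-protein pooled variances (at least 10 positive
#'   entries).
#' @param df Residual degrees of freedom, scalar or per-protein vector.
#' @return A list with `d0` (prior degrees of freedom, possibly `Inf`) and
#'   `s0_sq` (prior variance).
#' @export
estimate_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 10L) stop("need at least 10 proteins with positive variance")
  s2u <- s2[ok]; dfu <- df[ok]
  z <- log(s2u)
  if (stats::var(z) == 0) {
    # all observed variances identical: no dispersion to moderate
    return(list(d0 = Inf, s0_sq = s2u[1L]))
  }
  e <- z - digamma(dfu / 2) + log(dfu / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(dfu / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated t-statistics and p-values
#'
#' Shrinks each per-protein variance toward the prior,
#' `s2_post = (d0 * s0_sq + df * s2) / (d0 + df)` (with `s2_post = s0_sq`
#' at `d0 = Inf`), and tests `effect / sqrt(s2_post * (1/n1 + 1/n2))`
#' against a t distribution with `df + d0` degrees of freedom (standard
#' normal when `d0 = Inf`), two-sided.
#'
#' @param effect Per-protein mean difference (group2 - group1).
#' @param s2 Per-protein pooled variances.
#' @param df Residual degrees of freedom (scalar or vector).
#' @param d0,s0_sq Prior parameters from [estimate_prior()].
#' @param n1,n2 Group sizes.
#' @return A data.frame with `s2_post`, `t_mod`, `p`.
#' @export
moderated_t <- function(effect, s2, df, d0, s0_sq, n1, n2) {
  df <- rep_len(df, length(effect))
  s2_post <- if (is.infinite(d0)) {
    rep_len(s0_sq, length(effect))
  } else {
    (d0 * s0_sq + df * s2) / (d0 + df)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- numeric(length(effect))
  zero_se <- se == 0
  t_mod[!zero_se] <- effect[!zero_se] / se[!zero_se]
  if (any(zero_se & effect != 0)) {
    warning("zero posterior variance with nonzero effect; p set to 0")
    t_mod[zero_se & effect != 0] <- Inf * sign(effect[zero_se & effect != 0])
  }
  df_total <- df + d0
  p <- 2 * stats::pt(abs(t_mod), df = df_total, lower.tail = FALSE)
  p[zero_se & effect == 0] <- 1
  data.frame(s2_post = s2_post, t_mod = t_mod, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} (m * p_(j) / j)`, capped at 1 and returned in the
#' input order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return The adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Two-group moderated differential expression
#'
#' Runs the full chain [fit_two_group()] -> [estimate_prior()] ->
#' [moderated_t()] -> [bh_adjust()] -> [call_deps()]. With
#' `moderation = FALSE` the ordinary pooled two-sample t-test is used
#' (`s2_post = s2`, `df` unchanged) — a screening mode reported without
#' the empirical-Bayes shrinkage.
#'
#' @param qm A complete log2-scale [quant_matrix()].
#' @param meta Sample metadata.
#' @param group1,group2 Group labels; effect is `group2 - group1`.
#' @param fdr DEP significance threshold on the BH q-value (default 0.05).
#' @param moderation Apply empirical-Bayes variance moderation?
#' @return A `ModeratedTestResult`: data.frame with per-protein
#'   `protein_id`, `effect`, `s2`, `df`, `s2_post`, `t_mod`, `p`, `q`,
#'   `call`; attributes `d0`, `s0_sq`, `n_up`, `n_down`, `fdr`.
#' @export
#' @examples
#' sim <- simulate_cohorts(sim_config(n_proteins = 200,
#'   design = data.frame(cohort = "A", group = c("NHA", "ACC"),
#'                       n = c(6L, 6L)),
#'   batch_shift_log2 = 0, seed = 3))
#' res <- moderated_de(log2_transform(sim$matrix), sim$metadata,
#'                     "NHA", "ACC")
#' attr(res, "n_up"); attr(res, "n_down")
moderated_de <- function(qm, meta, group1, group2, fdr = 0.05,
                         moderation = TRUE) {
  fit <- fit_two_group(qm, meta, group1, group2)
  n1 <- attr(fit, "n1"); n2 <- attr(fit, "n2")
  if (moderation) {
    prior <- estimate_prior(fit$s2, fit$df)
  } else {
    prior <- list(d0 = 0, s0_sq = mean(fit$s2))
  }
  mt <- moderated_t(fit$effect, fit$s2, fit$df, prior$d0, prior$s0_sq,
                    n1, n2)
  out <- cbind(fit, mt)
  out$q <- bh_adjust(out$p)
  out <- call_deps(out, fdr = fdr)
  attr(out, "d0") <- prior$d0
  attr(out, "s0_sq") <- prior$s0_sq
  attr(out, "n1") <- n1
  attr(out, "n2") <- n2
  class(out) <- c("ModeratedTestResult", "data.frame")
  out
}

#' Call differentially expressed proteins
#'
#' A protein is called `up` iff `q < fdr` and its effect is positive,
#' `down` iff `q < fdr` and negative, otherwise `none`.
#'
#' @param result Data.frame with columns `q` and `effect`.
#' @param fdr Significance threshold (default 0.05).
#' @return `result` with a `call` column and attributes `n_up`, `n_down`,
#'   `fdr`.
#' @export
call_deps <- function(result, fdr = 0.05) {
  stopifnot(all(c("q", "effect") %in% names(result)))
  call <- rep("none", nrow(result))
  call[result$q < fdr & result$effect > 0] <- "up"
  call[result$q < fdr & result$effect < 0] <- "down"
  result$call <- call
  attr(result, "n_up") <- sum(call == "up")
  attr(result, "n_down") <- sum(call == "down")
  attr(result, "fdr") <- fdr
  result
}

#' @export
print.ModeratedTestResult <- function(x, ...) {
  cat(sprintf(
    "ModeratedTestResult: %d proteins, d0 = %s, s0_sq = %.4g\n",
    nrow(x), format(attr(x, "d0"), digits = 4), attr(x, "s0_sq")))
  cat(sprintf("  DEPs at FDR %.2g: %d up, %d down\n", attr(x, "fdr"),
              attr(x, "n_up"), attr(x, "n_down")))
  invisible(x)
}
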