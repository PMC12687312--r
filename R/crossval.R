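#' Stratified fold assignment
#'
#' Samples are shuffled within each (cohort, group) stratum under the seed
#' and dealt round-robin to `k` folds, so within every stratum the fold
#' sizes differ by at most one (58 samples at k = 4 give 15/15/14/14,
#' 8 give 2/2/2/2).
#'
#' @param meta Sample metadata.
#' @param k Number of folds (default 4).
#' @param seed Integer seed for the within-stratum shuffles.
#' @param allow_small Allow strata with fewer than `k` samples (some folds
#'   then receive no sample from that stratum)? Default `FALSE`: such a
#'   stratum is an error.
#' @return A `FoldPlan` list: `k`, `assignment` (named integer vector,
#'   sample_id -> fold), `strata`, `seed`.
#' @export
make_stratified_folds <- function(meta, k = 4L, seed = 1L,
                                  allow_small = FALSE) {
  meta <- sample_metadata(meta)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  strata <- paste(meta$cohort, meta$group, sep = "/")
  sizes <- table(strata)
  if (!allow_small && any(sizes < k)) {
    stop("stratum smaller than k folds: ",
         paste(names(sizes)[sizes < k], collapse = ", "),
         " (use allow_small = TRUE to override)")
  }
  set.seed(seed)
  assignment <- integer(nrow(meta))
  names(assignment) <- meta$sample_id
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    assignment[idx] <- ((seq_along(idx) - 1L) %% k) + 1L
  }
  structure(list(k = k, assignment = assignment,
                 strata = sort(unique(strata)), seed = as.integer(seed)),
            class = "FoldPlan")
}

#' Cross-validated cross-cohort robustness per protein
#'
#' For each fold f the samples in f form the test set and the rest the
#' training set; the per-protein cross-cohort mean difference
#' `d_g = mean_A(g) - mean_B(g)` is computed on both. Across the k folds:
#' `corr_g` is the Pearson correlation between training and test
#' estimates (0 when either side is constant across folds — no evidence of
#' co-variation); `stability_g = 1 - sd(d_test) / (|mean(d_test)| + eps)`
#' clamped to `[0, 1]` with `eps = 1e-8`, except that a protein whose test
#' estimates have both sd and |mean| below `eps` is perfectly stable at
#' zero and scores 1. The composite is
#' `0.5 * (corr_g + 1) / 2 + 0.5 * stability_g` and proteins are ranked by
#' descending composite, ties broken by protein id.
#'
#' @param qm A complete log2-scale [quant_matrix()] (preprocessing done).
#' @param meta Sample metadata.
#' @param plan A [make_stratified_folds()] plan with `k >= 3`.
#' @param cohortA,cohortB Cohort labels.
#' @return A `CrossValResult` data.frame: `protein_id`, `corr`,
#'   `stability`, `composite`, `rank`, plus per-fold estimate matrices in
#'   attributes `d_train`, `d_test`.
#' @export
crossval_concordance <- function(qm, meta, plan, cohortA, cohortB) {
  validate_quant_matrix(qm)
  if (!all(qm$mask)) stop("crossval expects a complete matrix")
  if (!inherits(plan, "FoldPlan")) stop("plan must be a FoldPlan")
  if (plan$k < 3L) stop("k must be at least 3 for fold-wise correlation")
  meta <- match_metadata(qm, meta)
  fold <- plan$assignment[meta$sample_id]
  if (anyNA(fold)) stop("fold plan does not cover every sample")
  p <- nrow(qm$values)
  d_train <- d_test <- matrix(NA_real_, p, plan$k)
  for (f in seq_len(plan$k)) {
    test <- fold == f
    for (side in c("train", "test")) {
      sel <- if (side == "train") !test else test
      ia <- which(sel & meta$cohort == cohortA)
      ib <- which(sel & meta$cohort == cohortB)
      if (!length(ia) || !length(ib)) {
        stop(sprintf("fold %d has no %s samples from both cohorts", f, side))
      }
      d <- rowMeans(qm$values[, ia, drop = FALSE]) -
        rowMeans(qm$values[, ib, drop = FALSE])
      if (side == "train") d_train[, f] <- d else d_test[, f] <- d
    }
  }
  eps <- 1e-8
  corr <- vapply(seq_len(p), function(g) {
    if (stats::sd(d_train[g, ]) == 0 || stats::sd(d_test[g, ]) == 0) {
      return(0)
    }
    stats::cor(d_train[g, ], d_test[g, ])
  }, numeric(1))
  mu <- rowMeans(d_test)
  sd_t <- apply(d_test, 1L, stats::sd)
  stability <- ifelse(sd_t < eps & abs(mu) < eps, 1,
                      pmin(pmax(1 - sd_t / (abs(mu) + eps), 0), 1))
  composite <- 0.5 * (corr + 1) / 2 + 0.5 * stability
  ord <- order(-composite, qm$protein_ids)
  rank <- integer(p)
  rank[ord] <- seq_len(p)
  out <- data.frame(protein_id = qm$protein_ids, corr = corr,
                    stability = stability, composite = composite,
                    rank = rank, stringsAsFactors = FALSE)
  attr(out, "d_train") <- d_train
  attr(out, "d_test") <- d_test
  attr(out, "plan") <- plan
  class(out) <- c("CrossValResult", "data.frame")
  out
}

#' Top-ranked proteins from a cross-validation result
#'
#' @param result A [crossval_concordance()] result.
#' @param top_n Number of proteins to report; larger than the table
#'   returns the full ranking.
#' @return The `top_n` rows ordered by rank (descending composite, ties
#'   by protein id).
#' @export
crossval_report <- function(result, top_n = 50L) {
  stopifnot(inherits(result, "CrossValResult"))
  ord <- order(result$rank)
  utils::head(as.data.frame(result)[ord, , drop = FALSE],
              min(top_n, nrow(result)))
}
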