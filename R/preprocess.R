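#' Valid-value filter rule
#'
#' Two filtering rules are used at different stages of the analysis:
#' \describe{
#'   \item{`any_group`}{keep a protein if it is observed in at least
#'     `min_fraction` (default 60%) of the samples of at least one
#'     biological group — the within-study identification filter.}
#'   \item{`each_cohort`}{keep a protein if it is observed in at least
#'     `min_fraction` (default 35%) of the samples of every cohort — the
#'     cross-cohort comparability filter.}
#' }
#'
#' @param mode `"any_group"` or `"each_cohort"`.
#' @param min_fraction Required observed fraction, in `(0, 1]`. Defaults to
#'   0.60 for `any_group` and 0.35 for `each_cohort`.
#' @return A `filter_rule` list.
#' @export
filter_rule <- function(mode = c("any_group", "each_cohort"),
                        min_fraction = NULL) {
  mode <- match.arg(mode)
  if (is.null(min_fraction)) {
    min_fraction <- if (mode == "any_group") 0.60 else 0.35
  }
  stopifnot(min_fraction > 0, min_fraction <= 1)
  structure(list(mode = mode, min_fraction = min_fraction,
                 key = if (mode == "any_group") "group" else "cohort"),
            class = "filter_rule")
}

#' Filter proteins by observed-value fraction
#'
#' Applies a [filter_rule()] to the observation mask: under `any_group` a
#' protein is kept iff some group reaches the required observed fraction;
#' under `each_cohort` iff every cohort does. Row order is preserved and
#' values are untouched.
#'
#' @param qm A [quant_matrix()].
#' @param meta Sample metadata covering every sample in `qm`.
#' @param rule A [filter_rule()].
#' @return The filtered [quant_matrix()].
#' @export
filter_by_valid_fraction <- function(qm, meta, rule = filter_rule()) {
  validate_quant_matrix(qm)
  if (!inherits(rule, "filter_rule")) stop("rule must be a filter_rule()")
  meta <- match_metadata(qm, meta)
  strata <- meta[[rule$key]]
  frac <- vapply(unique(strata), function(s) {
    cols <- which(strata == s)
    rowMeans(qm$mask[, cols, drop = FALSE])
  }, numeric(nrow(qm$values)))
  frac <- matrix(frac, nrow = nrow(qm$values))
  keep <- if (rule$mode == "any_group") {
    apply(frac >= rule$min_fraction, 1L, any)
  } else {
    apply(frac >= rule$min_fraction, 1L, all)
  }
  if (!any(keep)) warning("filter removed every protein")
  quant_matrix(qm$values[keep, , drop = FALSE],
               protein_ids = qm$protein_ids[keep],
               sample_ids = qm$sample_ids,
               mask = qm$mask[keep, , drop = FALSE], scale = qm$scale)
}

#' Log2-transform a raw-scale matrix
#'
#' Observed cells are replaced by `log2(value)`; the scale flag flips to
#' `"log2"`, which blocks a second (double) transform. Masked cells are
#' unchanged.
#'
#' @param qm A raw-scale [quant_matrix()] with strictly positive observed
#'   values.
#' @return The log2-scale matrix.
#' @export
log2_transform <- function(qm) {
  validate_quant_matrix(qm)
  if (qm$scale == "log2") stop("matrix is already on the log2 scale")
  if (any(qm$values[qm$mask] <= 0)) {
    stop("log2 transform requires strictly positive observed values")
  }
  vals <- qm$values
  vals[qm$mask] <- log2(vals[qm$mask])
  quant_matrix(vals, protein_ids = qm$protein_ids,
               sample_ids = qm$sample_ids, mask = qm$mask, scale = "log2")
}

#' Quantile-normalize sample columns
#'
#' Forces every sample column onto the common mean quantile curve. The
#' reference curve is built on a grid of `nrow(qm)` probabilities: each
#' column's observed values are sorted and linearly interpolated onto the
#' grid, and the curves are averaged across columns. Each observed value is
#' then replaced by the reference curve evaluated at its fractional rank
#' `(rank - 1) / (n_observed - 1)` within its column, with average ranks
#' for ties (tied values therefore receive the mean of their spanned
#' reference quantiles). Columns with complete data end up with identical
#' sorted value multisets; missing cells stay missing.
#'
#' @param qm A log2-scale [quant_matrix()]; every column needs at least two
#'   observed values.
#' @return The normalized matrix.
#' @export
quantile_normalize <- function(qm) {
  validate_quant_matrix(qm)
  if (qm$scale != "log2") stop("quantile normalization expects log2 scale")
  n <- nrow(qm$values)
  if (n < 2L) stop("need at least two proteins to normalize")
  n_obs <- colSums(qm$mask)
  if (any(n_obs < 2L)) {
    stop("column(s) with fewer than 2 observed values: ",
         paste(qm$sample_ids[n_obs < 2L], collapse = ", "))
  }
  grid <- seq(0, 1, length.out = n)
  curves <- vapply(seq_len(ncol(qm$values)), function(j) {
    o <- sort(qm$values[qm$mask[, j], j])
    stats::approx(seq(0, 1, length.out = length(o)), o, xout = grid)$y
  }, numeric(n))
  ref <- rowMeans(curves)
  vals <- qm$values
  for (j in seq_len(ncol(vals))) {
    obs <- qm$mask[, j]
    x <- vals[obs, j]
    pos <- (rank(x, ties.method = "average") - 1) / (length(x) - 1)
    vals[obs, j] <- stats::approx(grid, ref, xout = pos)$y
  }
  quant_matrix(vals, protein_ids = qm$protein_ids,
               sample_ids = qm$sample_ids, mask = qm$mask, scale = "log2")
}

#' Impute missing values by iterative low-rank (PCA) completion
#'
#' Missing cells are initialized at their row means, then the algorithm
#' alternates between (i) a rank-`n_components` SVD approximation of the
#' row-centered completed matrix and (ii) overwriting only the missing
#' cells with the approximation (row means restored), until the largest
#' absolute change at a missing cell drops below `tol` or `max_iter` is
#' reached. Observed cells are bit-identical to the input; the returned
#' mask is all-observed, with the set of imputed cells recorded in the
#' `imputed` field.
#'
#' @param qm A log2-scale [quant_matrix()]; every row and column must have
#'   at least one observed value.
#' @param n_components Rank of the completion model (default 2); must be
#'   smaller than both dimensions.
#' @param max_iter Maximum number of alternations (default 500).
#' @param tol Convergence tolerance on the missing cells (default 1e-6).
#' @param seed Ignored; the SVD completion is deterministic. Accepted for
#'   interface stability.
#' @return A complete [quant_matrix()] with the `imputed` record.
#' @export
pca_impute <- function(qm, n_components = 2L, max_iter = 500L, tol = 1e-6,
                       seed = NULL) {
  validate_quant_matrix(qm)
  if (qm$scale != "log2") stop("pca_impute expects a log2-scale matrix")
  k <- as.integer(n_components)
  if (k < 1L || k >= min(dim(qm$values))) {
    stop("n_components must be in [1, min(dim) - 1]")
  }
  miss <- !qm$mask
  if (!any(miss)) {
    out <- qm
    out$imputed <- matrix(FALSE, nrow(qm$values), ncol(qm$values),
                          dimnames = dimnames(qm$values))
    return(out)
  }
  empty_row <- rowSums(qm$mask) == 0L
  empty_col <- colSums(qm$mask) == 0L
  if (any(empty_row)) {
    stop("row(s) with no observed value: ",
         paste(qm$protein_ids[empty_row], collapse = ", "))
  }
  if (any(empty_col)) {
    stop("column(s) with no observed value: ",
         paste(qm$sample_ids[empty_col], collapse = ", "))
  }
  x <- qm$values
  init <- rowMeans(x, na.rm = TRUE)
  for (i in which(rowSums(miss) > 0L)) x[i, miss[i, ]] <- init[i]
  delta <- Inf
  for (iter in seq_len(max_iter)) {
    rm_ <- rowMeans(x)
    sv <- svd(x - rm_, nu = k, nv = k)
    approx_x <- sv$u %*% (sv$d[seq_len(k)] * t(sv$v)) + rm_
    delta <- max(abs(approx_x[miss] - x[miss]))
    x[miss] <- approx_x[miss]
    if (delta < tol) break
  }
  if (delta >= tol) {
    warning(sprintf("pca_impute did not converge in %d iterations (delta %.3g)",
                    max_iter, delta))
  }
  x[qm$mask] <- qm$values[qm$mask]
  quant_matrix(x, protein_ids = qm$protein_ids, sample_ids = qm$sample_ids,
               mask = matrix(TRUE, nrow(x), ncol(x)), scale = "log2",
               imputed = structure(miss, dimnames = dimnames(x)))
}

#' Cohort-level batch centering
#'
#' Removes a single scalar per cohort: each cohort's grand mean over its
#' observed cells is subtracted from that cohort's cells and the global
#' grand mean is added back, so per-protein between-cohort contrasts are
#' preserved up to one scalar. This targets a cohort-level technical shift
#' without touching per-protein biology (per-protein centering would erase
#' the very cross-cohort differences the concordance analysis measures).
#'
#' @param qm A log2-scale [quant_matrix()].
#' @param meta Sample metadata covering every sample.
#' @return The centered matrix.
#' @export
center_cohorts <- function(qm, meta) {
  validate_quant_matrix(qm)
  if (qm$scale != "log2") stop("center_cohorts expects a log2-scale matrix")
  meta <- match_metadata(qm, meta)
  vals <- qm$values
  global_mean <- mean(vals[qm$mask])
  for (coh in unique(meta$cohort)) {
    cols <- which(meta$cohort == coh)
    obs <- qm$mask[, cols, drop = FALSE]
    if (!any(obs)) stop("cohort with no observed cells: ", coh)
    block <- vals[, cols, drop = FALSE]
    block[obs] <- block[obs] - mean(block[obs]) + global_mean
    vals[, cols] <- block
  }
  quant_matrix(vals, protein_ids = qm$protein_ids,
               sample_ids = qm$sample_ids, mask = qm$mask, scale = "log2",
               imputed = qm$imputed)
}

#' Principal-component scores of the samples
#'
#' Scores of the samples on the first `n_components` principal components
#' of the protein-centered matrix (each protein's mean subtracted), via
#' SVD. Sign convention: within each component the protein loading of
#' largest absolute value is made positive, so scores are deterministic.
#'
#' @param qm A complete (post-imputation) log2-scale [quant_matrix()].
#' @param n_components Number of components (default 2).
#' @return A data.frame with `sample_id` and `PC1..PCk` score columns;
#'   the proportion of variance explained is attached as attribute
#'   `var_explained`.
#' @export
pca_scores <- function(qm, n_components = 2L) {
  validate_quant_matrix(qm)
  if (!all(qm$mask)) stop("matrix has missing cells; impute first")
  k <- as.integer(n_components)
  xc <- qm$values - rowMeans(qm$values)
  sv <- svd(xc)
  k <- min(k, length(sv$d))
  for (i in seq_len(k)) {
    j <- which.max(abs(sv$u[, i]))
    if (sv$u[j, i] < 0) {
      sv$u[, i] <- -sv$u[, i]
      sv$v[, i] <- -sv$v[, i]
    }
  }
  scores <- sv$v[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  colnames(scores) <- paste0("PC", seq_len(k))
  out <- data.frame(sample_id = qm$sample_ids, scores,
                    stringsAsFactors = FALSE)
  attr(out, "var_explained") <- sv$d[seq_len(k)]^2 / sum(sv$d^2)
  out
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper enforcing the stage order
#' filter -> log2 -> quantile normalize -> PCA impute -> (optional) cohort
#' centering. Scale flags make it impossible to apply stages out of order.
#'
#' @param qm A raw-scale [quant_matrix()].
#' @param meta Sample metadata.
#' @param rule A [filter_rule()].
#' @param n_components Rank for [pca_impute()].
#' @param batch_center Apply [center_cohorts()] after imputation?
#' @return A complete log2-scale [quant_matrix()]; a `preprocess_log`
#'   attribute records proteins dropped and cells imputed.
#' @export
preprocess_pipeline <- function(qm, meta, rule = filter_rule("each_cohort"),
                                n_components = 2L, batch_center = TRUE) {
  n0 <- nrow(qm$values)
  qm <- filter_by_valid_fraction(qm, meta, rule)
  qm <- log2_transform(qm)
  qm <- quantile_normalize(qm)
  qm <- pca_impute(qm, n_components = n_components)
  n_imp <- sum(qm$imputed)
  if (batch_center) qm <- center_cohorts(qm, meta)
  attr(qm, "preprocess_log") <- list(
    proteins_in = n0, proteins_kept = nrow(qm$values),
    cells_imputed = n_imp, rule = rule$mode,
    min_fraction = rule$min_fraction, batch_center = batch_center)
  qm
}
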