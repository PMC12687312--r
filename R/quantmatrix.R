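#' Protein quantification matrix with explicit missingness
#'
#' A `QuantMatrix` holds a proteins x samples abundance matrix together with
#' a logical observation mask and a scale flag. It is the object every
#' pipeline stage consumes and produces. Values at unobserved (masked-out)
#' cells are stored as `NA` and carry no numeric meaning; observed raw-scale
#' intensities must be strictly positive so that the log2 transform is
#' well defined.
#'
#' @param values Numeric matrix, rows = protein groups, columns = samples.
#'   `NA` entries are taken as missing unless `mask` says otherwise.
#' @param protein_ids Character vector of unique protein accessions
#'   (defaults to `rownames(values)`).
#' @param sample_ids Character vector of unique sample names
#'   (defaults to `colnames(values)`).
#' @param mask Logical matrix, `TRUE` where a value was observed. Defaults
#'   to `!is.na(values)`.
#' @param scale Either `"raw"` (intensities) or `"log2"`. The flag is what
#'   prevents a double log2 transform.
#' @param imputed Optional logical matrix recording which cells were filled
#'   in by imputation.
#'
#' @return An object of class `QuantMatrix`: a list with elements
#'   `values`, `mask`, `protein_ids`, `sample_ids`, `scale` and
#'   (optionally) `imputed`.
#' @export
#' @examples
#' m <- matrix(c(4, 8, NA, 16), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("s1", "s2")))
#' qm <- quant_matrix(m)
#' n_observed(qm)
quant_matrix <- function(values, protein_ids = rownames(values),
                         sample_ids = colnames(values),
                         mask = !is.na(values),
                         scale = c("raw", "log2"),
                         imputed = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(protein_ids)) {
    stop("protein ids are required (rownames or `protein_ids`)")
  }
  if (is.null(sample_ids)) {
    stop("sample ids are required (colnames or `sample_ids`)")
  }
  mask <- as.matrix(mask)
  values[!mask] <- NA_real_
  dimnames(values) <- list(protein_ids, sample_ids)
  dimnames(mask) <- dimnames(values)
  qm <- structure(
    list(values = values, mask = mask,
         protein_ids = as.character(protein_ids),
         sample_ids = as.character(sample_ids),
         scale = scale, imputed = imputed),
    class = "QuantMatrix")
  validate_quant_matrix(qm)
  qm
}

validate_quant_matrix <- function(qm) {
  stopifnot(inherits(qm, "QuantMatrix"))
  v <- qm$values
  if (length(qm$protein_ids) != nrow(v)) {
    stop("protein_ids length does not match number of rows")
  }
  if (length(qm$sample_ids) != ncol(v)) {
    stop("sample_ids length does not match number of columns")
  }
  if (anyDuplicated(qm$protein_ids)) {
    dup <- unique(qm$protein_ids[duplicated(qm$protein_ids)])
    stop("duplicate protein ids: ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(qm$sample_ids)) {
    dup <- unique(qm$sample_ids[duplicated(qm$sample_ids)])
    stop("duplicate sample ids: ", paste(dup, collapse = ", "))
  }
  if (!identical(dim(qm$mask), dim(v))) stop("mask dimensions differ from values")
  if (!is.logical(qm$mask) || anyNA(qm$mask)) stop("mask must be logical without NA")
  if (any(is.na(v[qm$mask]))) stop("observed cells must carry numeric values")
  if (qm$scale == "raw" && any(v[qm$mask] <= 0)) {
    stop("observed raw-scale intensities must be strictly positive")
  }
  if (!qm$scale %in% c("raw", "log2")) stop("scale must be 'raw' or 'log2'")
  invisible(qm)
}

#' @export
print.QuantMatrix <- function(x, ...) {
  cat(sprintf("QuantMatrix: %d proteins x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  observed cells: %d / %d (%.1f%%)\n", sum(x$mask),
              length(x$mask), 100 * mean(x$mask)))
  if (!is.null(x$imputed)) {
    cat(sprintf("  imputed cells: %d\n", sum(x$imputed)))
  }
  invisible(x)
}

#' @export
dim.QuantMatrix <- function(x) dim(x$values)

#' Number of observed cells
#' @param qm A [quant_matrix()].
#' @return Integer count of observed (unmasked) cells.
#' @export
n_observed <- function(qm) sum(qm$mask)

#' Validate a sample metadata table
#'
#' Sample metadata associates each sample with its cohort (study centre),
#' biological group (diagnosis) and an optional cross-validation fold.
#'
#' @param meta A data.frame with columns `sample_id`, `cohort`, `group`
#'   and optionally `fold`.
#' @return The validated data.frame (fold coerced to integer if present).
#' @export
sample_metadata <- function(meta) {
  req <- c("sample_id", "cohort", "group")
  missing_cols <- setdiff(req, names(meta))
  if (length(missing_cols)) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  meta$sample_id <- as.character(meta$sample_id)
  meta$cohort <- as.character(meta$cohort)
  meta$group <- as.character(meta$group)
  if (anyDuplicated(meta$sample_id)) {
    dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
    stop("duplicate sample_id in metadata: ", paste(dup, collapse = ", "))
  }
  if ("fold" %in% names(meta)) {
    meta$fold <- suppressWarnings(as.integer(meta$fold))
  }
  meta
}

# Align metadata rows to a QuantMatrix's samples, in sample order.
# strict = TRUE errors on samples without metadata (required by every
# analysis stage); strict = FALSE warns and drops them (I/O join check).
match_metadata <- function(qm, meta, strict = TRUE) {
  meta <- sample_metadata(meta)
  unmatched <- setdiff(qm$sample_ids, meta$sample_id)
  if (length(unmatched)) {
    msg <- paste0("samples without metadata: ",
                  paste(unmatched, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  idx <- match(qm$sample_ids, meta$sample_id)
  if (all(is.na(idx))) stop("no matrix sample has a metadata row")
  meta[idx[!is.na(idx)], , drop = FALSE]
}
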