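#' Read a wide protein quantification table
#'
#' Reads a proteins x samples abundance table into a [quant_matrix()].
#' Three dialects are supported:
#' \describe{
#'   \item{`generic_tsv` / `generic_csv`}{first column holds the protein
#'     accession, every remaining column is a sample. Only empty cells and
#'     `missing_tokens` are treated as missing.}
#'   \item{`diann_pg`}{a DIA-NN protein-group matrix (`pg_matrix` style):
#'     the `Protein.Group` column keys the rows, the annotation columns
#'     `Protein.Ids`, `Protein.Names`, `Genes` and
#'     `First.Protein.Description` are ignored if present, and every other
#'     column is a run. DIA-NN writes `0` for quantities it could not
#'     estimate, so in this dialect zeros are masked as missing alongside
#'     empty cells and `missing_tokens`.}
#' }
#' Protein-group strings are collapsed to their leader accession (the first
#' semicolon-separated token), giving deterministic unique keys.
#'
#' @param path Path to the table.
#' @param dialect One of `"generic_tsv"`, `"generic_csv"`, `"diann_pg"`.
#' @param missing_tokens Character cell contents treated as missing in
#'   addition to the empty string.
#' @return A [quant_matrix()] on the raw scale.
#' @export
read_quant_table <- function(path,
                             dialect = c("generic_tsv", "diann_pg",
                                         "generic_csv"),
                             missing_tokens = c("", "NA", "NaN")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "generic_csv") "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (nrow(tab) == 0L) stop("table has no data rows: ", path)
  if (dialect == "diann_pg") {
    if (!"Protein.Group" %in% names(tab)) {
      stop("diann_pg dialect requires a 'Protein.Group' column")
    }
    annot <- c("Protein.Group", "Protein.Ids", "Protein.Names", "Genes",
               "First.Protein.Description")
    ids <- tab[["Protein.Group"]]
    quant <- tab[, setdiff(names(tab), annot), drop = FALSE]
  } else {
    ids <- tab[[1L]]
    quant <- tab[, -1L, drop = FALSE]
  }
  if (ncol(quant) == 0L) stop("table has zero sample columns: ", path)
  # leader accession of each protein group
  ids <- sub(";.*$", "", ids)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate protein ids: ", paste(dup, collapse = ", "))
  }
  vals <- matrix(NA_real_, nrow(quant), ncol(quant),
                 dimnames = list(ids, names(quant)))
  for (j in seq_len(ncol(quant))) {
    cell <- quant[[j]]
    miss <- cell %in% missing_tokens
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!miss & is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric cell '%s' at row %d (protein %s), column '%s'",
                   cell[bad[1L]], bad[1L], ids[bad[1L]], names(quant)[j]))
    }
    if (dialect == "diann_pg") miss <- miss | (!is.na(num) & num == 0)
    num[miss] <- NA_real_
    vals[, j] <- num
  }
  quant_matrix(vals, scale = "raw")
}

#' Write a quantification table as canonical TSV
#'
#' UTF-8, tab-separated, protein ids in the first column (`protein_id`),
#' empty string for missing cells, full `%.17g` precision so that
#' `read_quant_table(write_quant_table(m))` is lossless. Output is
#' byte-stable for a given matrix.
#'
#' @param qm A [quant_matrix()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_quant_table <- function(qm, path) {
  validate_quant_matrix(qm)
  cells <- matrix("", nrow(qm$values), ncol(qm$values))
  obs <- qm$mask
  cells[obs] <- sprintf("%.17g", qm$values[obs])
  lines <- c(paste(c("protein_id", qm$sample_ids), collapse = "\t"),
             vapply(seq_len(nrow(cells)), function(i) {
               paste(c(qm$protein_ids[i], cells[i, ]), collapse = "\t")
             }, character(1)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects a TSV with header `sample_id`, `cohort`, `group` and an optional
#' `fold` column; validates uniqueness of `sample_id`.
#'
#' @param path Path to the metadata TSV.
#' @return A validated data.frame (see [sample_metadata()]).
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  sample_metadata(tab)
}

#' Write a sample metadata table
#' @param meta A metadata data.frame (see [sample_metadata()]).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_metadata <- function(meta, path) {
  meta <- sample_metadata(meta)
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Check that matrix samples and metadata agree
#'
#' Joins a quantification matrix against a metadata table and reports
#' matrix samples that have no metadata row (as a warning listing the ids).
#'
#' @param qm A [quant_matrix()].
#' @param meta A metadata data.frame.
#' @return Invisibly, the character vector of unmatched sample ids.
#' @export
check_metadata_join <- function(qm, meta) {
  meta <- sample_metadata(meta)
  unmatched <- setdiff(qm$sample_ids, meta$sample_id)
  if (length(unmatched)) {
    warning("samples without metadata: ", paste(unmatched, collapse = ", "))
  }
  invisible(unmatched)
}
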