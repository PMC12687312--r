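#' Default pipeline configuration
#'
#' Builds the configuration list consumed by [run_pipeline()], covering
#' input paths (or a simulation request), preprocessing options, contrast
#' definitions, GSI weights and cross-validation options. The whole object
#' is serializable to YAML/JSON; a run echoes its effective configuration
#' into the output directory.
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param quant_path,metadata_path Input tables; ignored when `simulate`
#'   is given.
#' @param simulate Optional [sim_config()] (or list of its fields): the
#'   run then starts by simulating its own input data.
#' @param rule,min_fraction Valid-value filter (see [filter_rule()]).
#' @param n_components Rank for [pca_impute()].
#' @param batch_center Apply [center_cohorts()]?
#' @param contrasts List of `c(group1, group2)` pairs for
#'   [moderated_de()].
#' @param fdr DEP threshold.
#' @param cohort_a,cohort_b Cohorts compared by [compute_gsi()] and
#'   [crossval_concordance()].
#' @param cv_k Number of cross-validation folds.
#' @param seed Global seed; per-stage seeds are derived from it by fixed
#'   offsets (simulation `seed`, missingness `seed + 1`, folds
#'   `seed + 3`), so stages are individually reproducible.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            quant_path = NULL, metadata_path = NULL,
                            simulate = NULL,
                            rule = "each_cohort", min_fraction = NULL,
                            n_components = 2L, batch_center = TRUE,
                            contrasts = list(c("NHA", "ACC")),
                            fdr = 0.05,
                            cohort_a = "USP", cohort_b = "SNUH",
                            cv_k = 4L, seed = 1L) {
  structure(list(out_dir = out_dir, quant_path = quant_path,
                 metadata_path = metadata_path, simulate = simulate,
                 rule = rule, min_fraction = min_fraction,
                 n_components = as.integer(n_components),
                 batch_center = isTRUE(batch_center),
                 contrasts = contrasts, fdr = fdr,
                 cohort_a = cohort_a, cohort_b = cohort_b,
                 cv_k = as.integer(cv_k), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' A small packaged demonstration configuration
#'
#' Simulated two-cohort data at reduced size (400 proteins) with the
#' default study design, suitable for a complete end-to-end run in a few
#' seconds.
#'
#' @param out_dir Output directory.
#' @param seed Global seed.
#' @return A [pipeline_config()].
#' @export
demo_config <- function(out_dir = tempfile("proteoconcord_demo_"),
                        seed = 1L) {
  pipeline_config(out_dir = out_dir,
                  simulate = sim_config(n_proteins = 400, seed = seed),
                  seed = seed)
}

#' Run the full analysis pipeline
#'
#' Executes (optional) simulate -> preprocess -> differential expression
#' per contrast -> cross-cohort concordance -> stratified cross-validation
#' and writes every stage's outputs under `config$out_dir`: quantification
#' / metadata / ground-truth TSVs (when simulated), the preprocessed
#' matrix, one `dea_<g1>_vs_<g2>.tsv` per contrast, the per-protein
#' concordance table, the cross-validation ranking and fold plan, a plain
#' one-line-per-stage log, the echoed configuration
#' (`run_config.yaml`) and a `summary.json` with the headline numbers.
#' Identical configuration and seed give identical outputs.
#'
#' @param config A [pipeline_config()] (or a path to a YAML/JSON file of
#'   its fields).
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config") || is.list(config))

  # validate inputs before any output is created
  if (is.null(config$simulate)) {
    if (is.null(config$quant_path) || !file.exists(config$quant_path)) {
      stop("quant table not found: ", config$quant_path)
    }
    if (is.null(config$metadata_path) || !file.exists(config$metadata_path)) {
      stop("metadata table not found: ", config$metadata_path)
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline_log.txt")
  log_lines <- character(0)
  log_stage <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    if (!inherits(sim_cfg, "sim_config")) sim_cfg <- do.call(sim_config, sim_cfg)
    sim <- simulate_cohorts(sim_cfg)
    qm <- inject_missingness(sim$matrix, sim_cfg)
    meta <- sim$metadata
    write_quant_table(qm, file.path(config$out_dir, "quant.tsv"))
    write_metadata(meta, file.path(config$out_dir, "metadata.tsv"))
    write_ground_truth(sim, file.path(config$out_dir, "ground_truth.tsv"))
    log_stage("simulate: %d proteins x %d samples, %.1f%% missing",
              nrow(qm$values), ncol(qm$values), 100 * mean(!qm$mask))
  } else {
    qm <- read_quant_table(config$quant_path)
    meta <- read_metadata(config$metadata_path)
    check_metadata_join(qm, meta)
    log_stage("read: %d proteins x %d samples from %s",
              nrow(qm$values), ncol(qm$values), config$quant_path)
  }

  rule <- filter_rule(config$rule, config$min_fraction)
  qm_pp <- preprocess_pipeline(qm, meta, rule = rule,
                               n_components = config$n_components,
                               batch_center = config$batch_center)
  pl <- attr(qm_pp, "preprocess_log")
  write_quant_table(qm_pp, file.path(config$out_dir, "preprocessed.tsv"))
  log_stage("preprocess: %d -> %d proteins (%s @ %.2f), %d cells imputed",
            pl$proteins_in, pl$proteins_kept, pl$rule, pl$min_fraction,
            pl$cells_imputed)

  dea_summaries <- list()
  for (ct in config$contrasts) {
    res <- moderated_de(qm_pp, meta, ct[1], ct[2], fdr = config$fdr)
    tag <- sprintf("%s_vs_%s", ct[1], ct[2])
    utils::write.table(as.data.frame(res),
                       file.path(config$out_dir, sprintf("dea_%s.tsv", tag)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dea_summaries[[tag]] <- list(n_up = attr(res, "n_up"),
                                 n_down = attr(res, "n_down"),
                                 d0 = attr(res, "d0"),
                                 s0_sq = attr(res, "s0_sq"))
    log_stage("dea %s: %d up, %d down at FDR %.2g", tag,
              attr(res, "n_up"), attr(res, "n_down"), config$fdr)
  }

  conc <- compute_gsi(qm_pp, meta, config$cohort_a, config$cohort_b)
  utils::write.table(conc$per_protein,
                     file.path(config$out_dir, "concordance_proteins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("concord: global GSI %.4f, mean psim %.2f%%",
            conc$global_gsi, conc$global_mean_psim)

  plan <- make_stratified_folds(meta, k = config$cv_k,
                                seed = config$seed + 3L)
  cv <- crossval_concordance(qm_pp, meta, plan, config$cohort_a,
                             config$cohort_b)
  utils::write.table(as.data.frame(cv),
                     file.path(config$out_dir, "crossval.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = names(plan$assignment),
                                fold = unname(plan$assignment)),
                     file.path(config$out_dir, "fold_plan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("cv: k = %d, median composite %.4f", plan$k,
            stats::median(cv$composite))

  summary <- list(
    proteins_in = pl$proteins_in, proteins_kept = pl$proteins_kept,
    cells_imputed = pl$cells_imputed, dea = dea_summaries,
    pearson = conc$pearson, icc = conc$icc,
    bland_altman = list(mean_d = conc$bland_altman$mean_d,
                        loa_low = conc$bland_altman$loa_low,
                        loa_high = conc$bland_altman$loa_high,
                        n_flagged = sum(conc$bland_altman$flag)),
    global_gsi = conc$global_gsi,
    global_mean_psim = conc$global_mean_psim,
    category_counts = as.list(conc$category_counts),
    cv_median_composite = stats::median(cv$composite),
    seed = config$seed)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_out <- config
  cfg_out$simulate <- if (is.null(config$simulate)) NULL else
    unclass(if (inherits(config$simulate, "sim_config")) config$simulate
            else do.call(sim_config, config$simulate))
  yaml::write_yaml(unclass(cfg_out),
                   file.path(config$out_dir, "run_config.yaml"))
  writeLines(log_lines, log_path)
  invisible(summary)
}

#' Read a pipeline configuration from YAML or JSON
#' @param path Configuration file path (`.yaml`/`.yml` or `.json`).
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$simulate) && !is.null(raw$simulate$design)) {
    raw$simulate$design <- as.data.frame(raw$simulate$design)
  }
  if (!is.null(raw$contrasts)) {
    raw$contrasts <- lapply(raw$contrasts, unlist)
  }
  do.call(pipeline_config, raw)
}
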