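#' Configuration for the two-cohort synthetic data generator
#'
#' The generator emulates the study design the package targets: two study
#' centres of very different size profiling the same tissue panel by
#' label-free DIA, with a tumour-vs-normal group structure, a cohort-level
#' batch shift, and both abundance-dependent (MNAR, left-censoring) and
#' completely-random (MCAR) missingness.
#'
#' The default design has cohort USP with 5 normal-adrenal (NHA) and
#' 8 carcinoma (ACC) samples and cohort SNUH with 58 ACC samples, and 3024
#' proteins — the post-filter cross-cohort comparison size. Protein
#' baselines are log-normal: baseline log2 abundance ~ N(20, 2) across
#' proteins with residual sd 0.5 within a protein, typical of DIA
#' protein-group intensities after search-engine rollup.
#'
#' @param n_proteins Number of protein groups.
#' @param design Data.frame with columns `cohort`, `group`, `n` giving the
#'   number of samples per (cohort, group) cell.
#' @param baseline_log2_mean,baseline_log2_sd Mean and sd (across proteins)
#'   of the per-protein baseline log2 abundance.
#' @param residual_sd Within-protein residual sd on the log2 scale.
#' @param dep_fraction Fraction of proteins that are true DEPs
#'   (differentially expressed in the tumour group), in `[0, 1]`.
#' @param dep_effect_log2 Absolute log2 effect of each DEP; the sign is
#'   drawn per protein.
#' @param tumor_group Group label receiving the DEP effect.
#' @param batch_shift_log2 Scalar added to every log2 value of
#'   `batch_cohort` (a cohort-level technical shift).
#' @param batch_cohort Cohort receiving the batch shift; defaults to the
#'   second cohort in `design`.
#' @param mnar_steepness,mnar_midpoint_log2 Parameters of the logistic
#'   left-censoring missingness curve used by [inject_missingness()].
#' @param mcar_rate Completely-random missingness rate in `[0, 1]`.
#' @param seed Integer seed; the generator is fully determined by it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_proteins = 3024,
                       design = data.frame(
                         cohort = c("USP", "USP", "SNUH"),
                         group = c("NHA", "ACC", "ACC"),
                         n = c(5L, 8L, 58L)),
                       baseline_log2_mean = 20,
                       baseline_log2_sd = 2,
                       residual_sd = 0.5,
                       dep_fraction = 0.05,
                       dep_effect_log2 = 1,
                       tumor_group = "ACC",
                       batch_shift_log2 = 0.5,
                       batch_cohort = NULL,
                       mnar_steepness = 1,
                       mnar_midpoint_log2 = 16,
                       mcar_rate = 0.02,
                       seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins), design = design,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              residual_sd = residual_sd, dep_fraction = dep_fraction,
              dep_effect_log2 = dep_effect_log2, tumor_group = tumor_group,
              batch_shift_log2 = batch_shift_log2,
              batch_cohort = batch_cohort,
              mnar_steepness = mnar_steepness,
              mnar_midpoint_log2 = mnar_midpoint_log2,
              mcar_rate = mcar_rate, seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_proteins >= 1,
            is.data.frame(cfg$design),
            all(c("cohort", "group", "n") %in% names(cfg$design)),
            all(cfg$design$n >= 1),
            cfg$baseline_log2_sd > 0, cfg$residual_sd >= 0,
            cfg$dep_fraction >= 0, cfg$dep_fraction <= 1,
            cfg$dep_effect_log2 >= 0,
            cfg$mnar_steepness >= 0,
            cfg$mcar_rate >= 0, cfg$mcar_rate <= 1)
  if (is.null(cfg$batch_cohort)) {
    cohorts <- unique(cfg$design$cohort)
    cfg$batch_cohort <- if (length(cohorts) >= 2) cohorts[2L] else NA_character_
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a two-cohort protein quantification data set
#'
#' Draws, in this fixed order from one RNG stream seeded by `config$seed`:
#' per-protein baselines, the DEP index set, DEP signs, then the residual
#' noise matrix. The log2 value of protein g in sample j is
#' `baseline_g + effect_g * [group_j == tumor] + batch_shift * [cohort_j ==
#' batch_cohort] + Normal(0, residual_sd)`. The matrix is returned on the
#' raw intensity scale (`2^log2`) and fully observed, so the pipeline's own
#' log2 step is exercised; use [inject_missingness()] to add missing cells.
#'
#' @param config A [sim_config()].
#' @return A list with elements `matrix` (a [quant_matrix()], raw scale,
#'   fully observed), `metadata` (sample metadata data.frame) and `truth`
#'   (list with `dep_index`, `dep_sign`, `true_effect_log2` per protein and
#'   `batch_shift_log2`).
#' @export
#' @examples
#' sim <- simulate_cohorts(sim_config(n_proteins = 50, seed = 7))
#' dim(sim$matrix)
simulate_cohorts <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  p <- config$n_proteins
  des <- config$design
  n_total <- sum(des$n)
  cohort <- rep(des$cohort, des$n)
  group <- rep(des$group, des$n)
  sample_id <- unlist(lapply(seq_len(nrow(des)), function(i) {
    sprintf("%s_%s_%02d", des$cohort[i], des$group[i], seq_len(des$n[i]))
  }))
  protein_id <- sprintf("P%05d", seq_len(p))

  baseline <- stats::rnorm(p, config$baseline_log2_mean, config$baseline_log2_sd)
  n_dep <- round(config$dep_fraction * p)
  dep_index <- if (n_dep > 0) sort(sample.int(p, n_dep)) else integer(0)
  dep_sign <- if (n_dep > 0) sample(c(-1, 1), n_dep, replace = TRUE) else numeric(0)
  true_effect <- numeric(p)
  true_effect[dep_index] <- dep_sign * config$dep_effect_log2

  in_batch <- if (is.na(config$batch_cohort)) {
    numeric(n_total)  # single-cohort design: no batch shift
  } else {
    as.numeric(cohort == config$batch_cohort)
  }
  log2v <- matrix(baseline, p, n_total) +
    outer(true_effect, as.numeric(group == config$tumor_group)) +
    config$batch_shift_log2 * matrix(in_batch, p, n_total, byrow = TRUE) +
    matrix(stats::rnorm(p * n_total, 0, config$residual_sd), p, n_total)
  dimnames(log2v) <- list(protein_id, sample_id)

  meta <- data.frame(sample_id = sample_id, cohort = cohort, group = group,
                     stringsAsFactors = FALSE)
  truth <- list(dep_index = dep_index, dep_sign = dep_sign,
                true_effect_log2 = true_effect,
                batch_shift_log2 = config$batch_shift_log2)
  list(matrix = quant_matrix(2^log2v, scale = "raw"),
       metadata = sample_metadata(meta), truth = truth)
}

#' Inject MNAR + MCAR missingness into a fully observed matrix
#'
#' Each cell is masked missing independently with probability
#' `mcar_rate + (1 - mcar_rate) * plogis(-mnar_steepness * (log2(value) -
#' mnar_midpoint_log2))`: a completely-random component plus a logistic
#' left-censoring component that preferentially removes low-abundance
#' measurements, the standard surrogate for intensity-dependent dropout in
#' DIA proteomics. Observed values are unchanged. The draw uses seed
#' `config$seed + 1` so it is reproducible yet independent of the value
#' simulation.
#'
#' @param qm A fully observed raw-scale [quant_matrix()].
#' @param config A [sim_config()].
#' @return The matrix with an updated mask.
#' @export
inject_missingness <- function(qm, config) {
  config <- validate_sim_config(config)
  validate_quant_matrix(qm)
  if (qm$scale != "raw") stop("inject_missingness expects a raw-scale matrix")
  if (!all(qm$mask)) stop("matrix already has missing cells")
  set.seed(config$seed + 1L)
  p_mnar <- stats::plogis(-config$mnar_steepness *
                            (log2(qm$values) - config$mnar_midpoint_log2))
  p_miss <- config$mcar_rate + (1 - config$mcar_rate) * p_mnar
  drop <- matrix(stats::runif(length(p_miss)) < p_miss, nrow(p_miss))
  vals <- qm$values
  vals[drop] <- NA_real_
  quant_matrix(vals, protein_ids = qm$protein_ids,
               sample_ids = qm$sample_ids, scale = "raw")
}

#' Write a ground-truth table for a simulation
#' @param sim Result of [simulate_cohorts()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(sim, path) {
  tab <- data.frame(protein_id = sim$matrix$protein_ids,
                    true_effect_log2 = sim$truth$true_effect_log2,
                    is_dep = seq_along(sim$matrix$protein_ids) %in%
                      sim$truth$dep_index)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
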