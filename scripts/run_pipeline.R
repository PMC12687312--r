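#!/usr/bin/env Rscript
# Thin command-line wrapper over proteoconcord::run_pipeline().
#
# Usage:
#   Rscript scripts/run_pipeline.R --config cfg.yaml
#   Rscript scripts/run_pipeline.R --demo --out out_dir --seed 1
#
# The configuration file (YAML or JSON) carries the fields of
# proteoconcord::pipeline_config(); --demo runs the packaged synthetic
# demonstration instead.

suppressPackageStartupMessages({
  library(optparse)
  library(proteoconcord)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--demo", action = "store_true", default = FALSE),
  make_option("--out", type = "character", default = "pipeline_out"),
  make_option("--seed", type = "integer", default = 1L)
)))

summary <- if (opts$demo) {
  run_pipeline(demo_config(out_dir = opts$out, seed = opts$seed))
} else if (!is.null(opts$config)) {
  run_pipeline(opts$config)
} else {
  stop("supply --config <file> or --demo")
}

cat(sprintf("global GSI %.4f | mean percent similarity %.2f%%\n",
            summary$global_gsi, summary$global_mean_psim))
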