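#!/usr/bin/env Rscript

# Thin shell entry point over patsim::run_pipeline(): simulate a dataset,
# preprocess, fit and compare the decision-value models, and build the
# model-based regressors, writing the artifact bundle to --out.
# Usage: Rscript scripts/run_pipeline.R --seed 1 --out runs/demo \
#          [--subjects 8] [--method pooled_ml] [--boot 200] [--replicates 0]

suppressPackageStartupMessages(library(patsim))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}

status <- tryCatch({
  cfg <- run_config(
    seed = as.integer(get_arg("--seed", stop("--seed is required"))),
    out_dir = get_arg("--out", "patsim-run"),
    n_subjects = as.integer(get_arg("--subjects", "8")),
    fit_method = get_arg("--method", "pooled_ml"),
    n_boot = as.integer(get_arg("--boot", "200")),
    n_replicates = as.integer(get_arg("--replicates", "0")))
  bundle <- run_pipeline(cfg)
  message("bundle written to ", cfg$out_dir)
  message(paste(bundle$log, collapse = "\n"))
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  if (grepl("config|seed|--", conditionMessage(e))) 2L else 1L
})
quit(status = status)
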