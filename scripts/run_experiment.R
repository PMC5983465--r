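#!/usr/bin/env Rscript
# Run a full PSA evaluation experiment from a YAML configuration:
#   Rscript scripts/run_experiment.R config.yaml [outdir]
# Writes the design, risk table, summary tables and manifest as CSV/JSON.

suppressMessages(library(psasim))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L)
  stop("usage: Rscript scripts/run_experiment.R config.yaml [outdir]")
cfg <- readExperimentConfig(args[1L])
if (length(args) >= 2L) cfg$outdir <- args[2L]
if (is.null(cfg$outdir)) cfg$outdir <- "psasim_results"

bundle <- runExperiment(cfg, progress = TRUE)
tables <- report(bundle, importance = TRUE)
message("similarity summary:")
print(tables$similarity)
message("accuracy summary:")
print(tables$accuracy)
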