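#!/usr/bin/env Rscript

# Thin shell wrapper over the package: simulate a study and/or run the full
# analysis pipeline on interchange files.
#
#   Rscript scripts/pipeline.R simulate --outdir sim --seed 1 [--n-genes 200]
#   Rscript scripts/pipeline.R run --probes sim/probes.tsv --gtf sim/genes.gtf \
#       --circs sim/circs.bed --peaks sim/peaks.bed --outdir out [--seed 1]
#   Rscript scripts/pipeline.R all --outdir out --seed 1   # simulate + run

suppressPackageStartupMessages({
  library(optparse)
  library(circm6a)
})

args <- commandArgs(trailingOnly = TRUE)
cmd <- if (length(args) >= 1) args[[1]] else ""
rest <- args[-1]

opt_list <- list(
  make_option("--outdir", type = "character", default = "out"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--n-genes", type = "integer", default = 200L, dest = "n_genes"),
  make_option("--probes", type = "character", default = NULL),
  make_option("--gtf", type = "character", default = NULL),
  make_option("--circs", type = "character", default = NULL),
  make_option("--peaks", type = "character", default = NULL),
  make_option("--fc-threshold", type = "double", default = 1.5, dest = "fc_threshold"),
  make_option("--p-threshold", type = "double", default = 0.05, dest = "p_threshold")
)
opts <- parse_args(OptionParser(option_list = opt_list), args = rest)

do_simulate <- function(dir) {
  sim <- simulate_study(sim_config(n_genes = opts$n_genes, seed = opts$seed))
  paths <- write_simulation(sim, dir)
  message("simulated study written to ", dir)
  paths
}

do_run <- function(paths) {
  cfg <- pipeline_config(
    paths[["probes"]], paths[["genes"]], paths[["circs"]], paths[["peaks"]],
    outdir = opts$outdir, fc_threshold = opts$fc_threshold,
    p_threshold = opts$p_threshold, seed = opts$seed
  )
  res <- run_pipeline(cfg)
  message(paste(res$log, collapse = "\n"))
}

if (cmd == "simulate") {
  do_simulate(opts$outdir)
} else if (cmd == "run") {
  stopifnot(!is.null(opts$probes), !is.null(opts$gtf),
            !is.null(opts$circs), !is.null(opts$peaks))
  do_run(c(probes = opts$probes, genes = opts$gtf,
           circs = opts$circs, peaks = opts$peaks))
} else if (cmd == "all") {
  paths <- do_simulate(file.path(opts$outdir, "sim"))
  do_run(paths)
} else {
  stop("usage: pipeline.R {simulate|run|all} [options]; see script header")
}
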