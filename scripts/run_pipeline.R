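#!/usr/bin/env Rscript

# Thin command-line wrapper over hlamatchr::run_pipeline().
# Usage:
#   Rscript scripts/run_pipeline.R [--config cfg.json] [--seed 1] \
#     [--out run_dir] [--stages simulate,ancestry,match,analyze,report] \
#     [--verbose]

suppressPackageStartupMessages({
  library(optparse)
  library(hlamatchr)
})

parser <- OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "JSON configuration (defaults to sim_config())"),
  make_option("--seed", type = "integer", default = NULL,
              help = "override the configuration's seed"),
  make_option("--out", type = "character", default = "hlamatchr_run",
              help = "output directory [default %default]"),
  make_option("--stages", type = "character",
              default = "simulate,ancestry,match,analyze,report",
              help = "comma-separated stage subset [default %default]"),
  make_option("--verbose", action = "store_true", default = FALSE,
              help = "structured progress logging")
))
opt <- parse_args(parser)

cfg <- if (is.null(opt$config)) sim_config() else read_sim_config(opt$config)
seed <- if (is.null(opt$seed)) cfg$seed else opt$seed
stages <- strsplit(opt$stages, ",", fixed = TRUE)[[1]]

manifest <- run_pipeline(cfg, opt$out, seed = seed, stages = stages,
                         verbose = opt$verbose)
cat("run complete; manifest at", file.path(opt$out, "manifest.json"), "\n")
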