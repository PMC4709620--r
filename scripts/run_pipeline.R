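#!/usr/bin/env Rscript
# Thin command-line wrapper over chromaPK::run_pipeline().
#   Rscript scripts/run_pipeline.R [--config cfg.yaml] [--seed 101]
#                                  [--out dir] [--stage all]
# Exit status: 0 all acceptance flags pass, 2 at least one flag failed,
# 1 configuration or runtime error.

suppressPackageStartupMessages({
  library(optparse)
  library(chromaPK)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML configuration; packaged defaults when omitted"),
  make_option("--seed", type = "integer", default = NULL,
              help = "master seed override"),
  make_option("--out", type = "character", default = NULL,
              help = "output directory override"),
  make_option("--stage", type = "character", default = "all",
              help = "simulate | sst | calibrate | validate | pk | all")
)))

res <- tryCatch(
  run_pipeline(config = opts$config, stage = opts$stage,
               seed = opts$seed, out_dir = opts$out),
  error = function(e) {
    message("error: ", conditionMessage(e))
    quit(status = 1L)
  })
quit(status = res$status)
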