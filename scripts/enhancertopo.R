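#!/usr/bin/env Rscript

# Thin command-line wrapper over enhancertopo::run_pipeline():
#   Rscript scripts/enhancertopo.R <subcommand> [--config cfg.json] [--seed N] [--out DIR]
# Subcommands: simulate, classify, diffsig, architecture, link, concordance,
# crossspecies, divisions, all. Flag values override the config file.

suppressPackageStartupMessages({
  library(optparse)
  library(enhancertopo)
})

parser <- OptionParser(
  usage = "%prog <subcommand> [options]",
  option_list = list(
    make_option("--config", type = "character", default = NULL,
                help = "JSON file of pipeline/simulation parameter overrides"),
    make_option("--seed", type = "integer", default = NULL,
                help = "simulation seed (overrides the config file)"),
    make_option("--out", type = "character", default = "enhancertopo_out",
                help = "output directory [default %default]")
  )
)
parsed <- parse_args(parser, positional_arguments = 1)
stage <- parsed$args

cfg_overrides <- list()
if (!is.null(parsed$options$config)) {
  cfg_overrides <- jsonlite::read_json(parsed$options$config, simplifyVector = TRUE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a
sim_over <- cfg_overrides$sim %||% list()
# JSON objects arrive as named lists; these parameters are named vectors
for (nm in intersect(c("chrom_sizes", "class_props"), names(sim_over))) {
  sim_over[[nm]] <- unlist(sim_over[[nm]])
}
pipe_over <- cfg_overrides[setdiff(names(cfg_overrides), "sim")]

config <- do.call(pipeline_config,
                  c(list(sim = do.call(sim_config, sim_over)), pipe_over))

status <- tryCatch({
  run_pipeline(stage, config, out_dir = parsed$options$out,
               seed = parsed$options$seed)
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  1L
})
quit(status = status)
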