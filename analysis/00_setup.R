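# Shared setup for the analysis drivers: resolve the run configuration
# once, create the results tree, and log the resolved settings. Every
# driver sources this file and uses only package functions for the
# computation itself.
#
# Override settings with a YAML file via the DERMOPSIN_CONFIG environment
# variable, or pass a seed as the first script argument.

library(dermopsin)

args <- commandArgs(trailingOnly = TRUE)
overrides <- list()
if (length(args) >= 1 && nzchar(args[[1]])) {
  overrides$seed <- as.integer(args[[1]])
}
cfg_file <- Sys.getenv("DERMOPSIN_CONFIG", "")
cfg <- run_config(file = if (nzchar(cfg_file)) cfg_file else NULL,
                  overrides = overrides)

results_dir <- "results"
for (d in file.path(results_dir, c("data", "tables", "spectra", "logs"))) {
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
}

msp_grid <- spectral_grid(cfg$grid_from, cfg$grid_to, cfg$grid_step)
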