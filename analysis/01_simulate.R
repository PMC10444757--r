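#!/usr/bin/env Rscript
# Generate the synthetic microspectrophotometry scan set (3 fish x 20
# cells x 3 chromatophore types by default) and the fixture SWS1 sequence
# pair, and write both in the on-disk layouts the downstream drivers read.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE)[1])),
                 "00_setup.R"), chdir = FALSE)

gen_cfg <- generator_config(
  n_fish = cfg$n_fish, cells_per_fish = cfg$cells_per_fish,
  grid = msp_grid, cv = cfg$cv, jitter_sd = cfg$jitter_sd,
  noise = cfg$noise, seed = cfg$seed)

scans <- generate_scans(gen_cfg)
scan_dir <- file.path(results_dir, "data", "scans")
write_scans(scans, scan_dir)

fx <- generate_fixture_sequences(cfg$substitutions)
Biostrings::writeXStringSet(
  fx, file.path(results_dir, "data", "fixture_sws1.fasta"))

log_config(cfg, file.path(results_dir, "logs", "01_simulate.yaml"))

types <- table(vapply(scans, `[[`, "", "chromatophore_type"))
cat(sprintf("wrote %d scans (%s) under %s\n", length(scans),
            paste(names(types), types, sep = "=", collapse = ", "),
            scan_dir))
cat(sprintf("wrote fixture pair (%s) differing at: %s\n",
            paste(names(fx), collapse = ", "),
            paste(cfg$substitutions, collapse = ", ")))
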