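#!/usr/bin/env Rscript
# Process the simulated scan directory into per-type mean transmittance
# spectra (with s.e.m.), transition wavelengths, and 415-nm-template
# attenuation fractions; write the per-type tables and spectra.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE)[1])),
                 "00_setup.R"), chdir = FALSE)

scans <- read_scans(file.path(results_dir, "data", "scans"))
template <- a1_template(cfg$template_lambda_max, msp_grid[msp_grid <= 520])

summaries <- summarize_types(scans, grid = msp_grid, template = template,
                             window_nm = cfg$window_nm,
                             min_slope = cfg$min_slope,
                             poly_order = cfg$poly_order)
tab <- summary_table(summaries)
write.table(tab, file.path(results_dir, "tables", "msp_summary.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

for (ty in names(summaries)) {
  write_spectrum(summaries[[ty]]$mean_T,
                 file.path(results_dir, "spectra",
                           paste0(ty, "_mean_T.tsv")))
  write_spectrum(summaries[[ty]]$sem_T,
                 file.path(results_dir, "spectra",
                           paste0(ty, "_sem_T.tsv")))
}

log_config(cfg, file.path(results_dir, "logs", "02_msp_summaries.yaml"))

cat("per-type summary (transition in nm; attenuation of 415-nm catch):\n")
print(tab, row.names = FALSE)
cat("\nmelanophores rise too gradually to show a transition (NA above);\n")
cat("all three pigments attenuate most strongly over the SWS1 band.\n")
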