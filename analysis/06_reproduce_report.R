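#!/usr/bin/env Rscript
# Collect the headline numbers of the full chain (run drivers 01-05 first)
# into one report table: the lambda_max estimate, per-type transition
# wavelengths and attenuations, and the feedback endpoints.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE)[1])),
                 "00_setup.R"), chdir = FALSE)

tables <- file.path(results_dir, "tables")
lmax <- read.table(file.path(tables, "lambda_max.tsv"), header = TRUE,
                   sep = "\t")
msp <- read.table(file.path(tables, "msp_summary.tsv"), header = TRUE,
                  sep = "\t")
ends <- read.table(file.path(tables, "feedback_endpoints.tsv"),
                   header = TRUE, sep = "\t")

report <- rbind(
  data.frame(quantity = "lambda_max_point_nm", value = lmax$point_nm),
  data.frame(quantity = "lambda_max_interval_low_nm",
             value = lmax$interval_low_nm),
  data.frame(quantity = "lambda_max_interval_high_nm",
             value = lmax$interval_high_nm),
  data.frame(quantity = paste0("transition_nm_", msp$type),
             value = msp$transition_nm),
  data.frame(quantity = paste0("attenuation_", msp$type),
             value = msp$attenuation_fraction),
  data.frame(quantity = paste0("dispersed_catch_", ends$type),
             value = ends$catch_dispersed))
write.table(report, file.path(tables, "reproduction_report.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

log_config(cfg, file.path(results_dir, "logs", "06_reproduce_report.yaml"))
print(report, row.names = FALSE)
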