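#!/usr/bin/env Rscript
# Map the fixture SWS1 sequence pair onto bovine rhodopsin numbering and
# call substitutions at the 13 packaged spectral tuning sites.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE)[1])),
                 "00_setup.R"), chdir = FALSE)

fx <- Biostrings::readAAStringSet(
  file.path(results_dir, "data", "fixture_sws1.fasta"))
anchor <- map_to_bovine(fx[1])
query <- map_to_bovine(fx[2])

subs <- compare_tuning_sites(anchor, query)
write_substitution_report(
  subs, file.path(results_dir, "tables", "tuning_substitutions.tsv"))

log_config(cfg, file.path(results_dir, "logs", "03_tuning_sites.yaml"))

cat(sprintf("%d of %d tuning sites differ between %s and %s:\n",
            nrow(subs), length(sws1_tuning_sites()),
            attr(anchor, "id"), attr(query, "id")))
print(subs, row.names = FALSE)
unc <- attr(subs, "uncallable")
if (length(unc) > 0) {
  cat("uncallable sites (gapped):", paste(unc, collapse = ", "), "\n")
} else {
  cat("all tuning sites were callable in both sequences\n")
}
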