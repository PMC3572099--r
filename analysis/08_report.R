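#!/usr/bin/env Rscript
# Collate the headline numbers of the preceding stages into a single JSON
# report (results/analysis/report.json).

source("analysis/_common.R")

read_out <- function(name) read.csv(file.path(OUT, name))

summ <- read_out("network_summary.csv")
jm <- read_out("jaccard.csv")
motifs <- read_out("motifs.csv")
burden <- read_out("burden.csv")
loc <- read_out("localization.csv")

report <- list(
  seed = SEED,
  network = as.list(summ),
  jaccard_theta_beta = jm[jm$isoform == "theta", "beta"],
  enriched_motif_classes = motifs$class_id[motifs$enriched],
  ffl_z = motifs$z[motifs$class_id == 7],
  max_acetylated_partners = burden$isoform[
    which.max(burden$acetylated_partners)],
  zeta_nls_concentration_p = loc$p_nls)
jsonlite::write_json(report, file.path(OUT, "report.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote ", file.path(OUT, "report.json"))
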