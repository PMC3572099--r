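#!/usr/bin/env Rscript
# Domain frequency heat-map data, the p <= 0.01 domain-isoform bipartite
# network, phospho- and acetyl-domain profiles, and clade (domain club)
# representation. The generator plants an RRM excess in gamma's partners.

source("analysis/_common.R")

inp <- load_inputs()
pn <- inp$pnets

freqs <- do.call(rbind, lapply(pn, domain_frequencies))
save_csv(freqs, "domain_frequencies.csv")

bip <- build_bipartite(pn, top_n = 10, alpha = 0.01)
print(bip)
save_csv(bip$edges, "domain_bipartite.csv")

rrm_freq <- vapply(pn, function(p) {
  f <- domain_frequencies(p)
  i <- match("RRM", f$domain_name)
  if (is.na(i)) 0 else f$frequency[i]
}, numeric(1))
pm <- domain_enrichment_tests(pn, "RRM")
message(sprintf("highest RRM carrier frequency: %s (%.2f; min pairwise p = %.2g)",
                names(which.max(rrm_freq)), max(rrm_freq),
                min(pm, na.rm = TRUE)))

save_csv(do.call(rbind, lapply(pn, modified_domain_frequencies,
                               modification = "phospho")),
         "phospho_domains.csv")
save_csv(do.call(rbind, lapply(pn, modified_domain_frequencies,
                               modification = "acetyl")),
         "acetyl_domains.csv")

cl <- do.call(rbind, lapply(names(pn), function(l) {
  cp <- clade_profile(pn[[l]])
  data.frame(isoform = l, n_unmapped = cp$n_unmapped,
             isolated_fraction = round(cp$isolated_fraction, 4))
}))
save_csv(cl, "clades.csv")
message("highest isolated-clade representation: ",
        cl$isoform[which.max(cl$isolated_fraction)])
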