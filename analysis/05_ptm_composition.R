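#!/usr/bin/env Rscript
# Region-stratified PTM composition per isoform network, cross-isoform
# acetylation burden, phospho/acetyl crosstalk, disorder comparison,
# kinase-group profiles and the acetylation/nuclear-localization link.

source("analysis/_common.R")

inp <- load_inputs()
pn <- inp$pnets

save_csv(do.call(rbind, lapply(pn, function(p)
  as.data.frame(composition_table(p)))), "composition.csv")

burden <- acetylation_burden(pn)
save_csv(burden$counts, "burden.csv")
save_csv(data.frame(isoform = rownames(burden$p_matrix),
                    signif(burden$p_matrix, 4)), "burden_pvalues.csv")
message("largest acetylated-partner count: ",
        burden$counts$isoform[which.max(burden$counts$acetylated_partners)])

ct <- do.call(rbind, lapply(names(pn), function(l)
  do.call(rbind, lapply(c("S", "T", "Y"), function(r) {
    res <- crosstalk_association(pn[[l]], r)
    data.frame(isoform = l, residue = r, p = res$p,
               degenerate = res$degenerate)
  }))))
save_csv(ct, "crosstalk.csv")

dis <- compare_disorder_content(pn)
message(sprintf("Kruskal-Wallis on disorder fractions: H = %.2f, p = %.3g",
                dis$kruskal$statistic, dis$kruskal$p))
save_csv(data.frame(isoform = rownames(dis$wilcoxon_p),
                    signif(dis$wilcoxon_p, 4)), "disorder_wilcoxon.csv")

kg <- kinase_group_profile(pn)
save_csv(data.frame(isoform = rownames(kg), round(unclass(kg), 4)),
         "kinase_groups.csv")

loc <- localization_stats(pn$zeta, function(prof) prof$n_acK > 0)
message(sprintf("zeta acetylated partners: %.0f%% of partners, %.0f%% of NLS, p = %.3g",
                100 * loc$fractions["subset_share"],
                100 * loc$fractions["nls_share"], loc$p))
save_csv(data.frame(t(loc$fractions), p_nls = loc$p), "localization.csv")
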