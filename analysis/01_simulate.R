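#!/usr/bin/env Rscript
# Generate the synthetic study cohort: seven 14-3-3 hub partner sets with a
# theta-beta overlap targeted at the published Jaccard, region-structured
# PTM sites, isoform-specific planted effects, kinase->substrate directions
# and a toy GO annotation. Writes every pipeline input format plus the
# ground truth under results/analysis/input.

source("analysis/_common.R")

bundle <- generate_bundle(analysis_config(), INPUT)
print(bundle)
message("planted effects: ",
        paste(names(bundle$truth$multipliers),
              unlist(bundle$truth$multipliers), sep = "=", collapse = ", "))
message("planted feed-forward loops: ",
        if (is.null(bundle$truth$planted_ffls)) 0 else
          nrow(bundle$truth$planted_ffls))
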