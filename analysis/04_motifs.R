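#!/usr/bin/env Rscript
# Directed 3-node motif census of the kinase/substrate layer against a
# degree-preserving switching ensemble. With the default generator the
# feed-forward loop (dictionary class 7) is planted and should come out
# enriched; on a null cohort no class should.

source("analysis/_common.R")

inp <- load_inputs()
dirs <- read.csv(file.path(OUT, "directed_edges.csv"))
hubs <- unname(isoform_accessions())
layer <- dirs[!(dirs$from %in% hubs | dirs$to %in% hubs),
              c("from", "to")]
ms <- motif_significance(layer, ensemble_size = 999L, seed = SEED + 10L)
save_csv(as.data.frame(ms), "motifs.csv")
print(as.data.frame(ms)[ms$count > 0,
                        c("class_id", "name", "count", "z", "p", "enriched")])
message("enriched classes: ",
        paste(ms$class_id[ms$enriched], collapse = ", "))
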