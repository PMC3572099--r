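#!/usr/bin/env Rscript
# Assemble the full 14-3-3 + kinase + substrate network from the input
# tables, extract the seven paralog subnetworks, and compare their partner
# sets with the Jaccard index. The theta-beta pair is expected to be the
# most similar (the generator targets the published 0.273).

source("analysis/_common.R")

inp <- load_inputs()
s <- summary(inp$net)
print(s)
save_csv(data.frame(nodes = s$n_nodes, edges = s$n_edges,
                    clients = s$n_clients), "network_summary.csv")

jm <- jaccard_matrix(inp$pnets)
print(jm)
save_csv(data.frame(isoform = rownames(jm), round(unclass(jm), 4)),
         "jaccard.csv")
write_network(inp$net, file.path(OUT, "network.graphml"))
message("most similar pair: ",
        paste(rownames(jm)[which(unclass(jm) == max(unclass(jm)[upper.tri(jm)]),
                                 arr.ind = TRUE)[1, ]], collapse = "-"))
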