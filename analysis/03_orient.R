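#!/usr/bin/env Rscript
# Orient every undirected interaction with the naive Bayes classifier
# trained on the curated kinase->substrate edges, keeping curated directions
# as-is, and report agreement with the generator's ground truth.

source("analysis/_common.R")

inp <- load_inputs()
model <- train_edge_classifier(inp$net, inp$train)
dnet <- orient_network(inp$net, model, curated = inp$train)
del <- directed_edgelist(dnet)
save_csv(cbind(del, posterior = round(dnet$edges$posterior, 6),
               curated = dnet$edges$curated), "directed_edges.csv")

truth <- read.delim(file.path(INPUT, "interactions.tsv"))  # context only
dir_truth <- jsonlite::read_json(file.path(INPUT, "truth.json"))
message(sprintf("oriented %d edges (%d curated)", nrow(del),
                sum(dnet$edges$curated)))
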