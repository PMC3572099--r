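# Shared settings for the numbered analysis scripts. Every script can be run
# on its own from the repository root (Rscript analysis/01_simulate.R ...);
# later scripts rebuild what they need from the files under results/analysis.

library(paralognet)

SEED <- as.integer(Sys.getenv("PARALOGNET_SEED", "1"))
OUT <- "results/analysis"
INPUT <- file.path(OUT, "input")
dir.create(OUT, showWarnings = FALSE, recursive = TRUE)

analysis_config <- function() sim_config(seed = SEED)

load_inputs <- function() {
  if (!file.exists(file.path(INPUT, "interactions.tsv")))
    stop("run analysis/01_simulate.R first")
  ann <- read_annotation_tables(
    domain_path = file.path(INPUT, "domains.tsv"),
    disorder_path = file.path(INPUT, "disorder.tsv"),
    go_path = file.path(INPUT, "go.tsv"),
    localization_path = file.path(INPUT, "localization.tsv"),
    kinase_group_path = file.path(INPUT, "kinase_groups.tsv"),
    clade_path = file.path(INPUT, "clades.tsv"))
  net <- assemble_full_network(
    read_interactions(file.path(INPUT, "interactions.tsv")), ann,
    read_ptm_table(file.path(INPUT, "ptm.tsv")),
    lengths = read.delim(file.path(INPUT, "lengths.tsv")))
  list(net = net, pnets = paralog_subnetworks(net),
       train = read.delim(file.path(INPUT, "train.tsv")),
       dag = read_obo(file.path(INPUT, "go.obo")),
       truth = jsonlite::read_json(file.path(INPUT, "truth.json")))
}

save_csv <- function(df, name) {
  p <- file.path(OUT, name)
  write.csv(df, p, row.names = FALSE)
  message("wrote ", p)
  p
}
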