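# Small in-code fixtures shared across test files.

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# A tiny hand-built annotated network: two hubs (beta, gamma), four partners
# with known domains, disorder and PTM sites, one kinase.
toy_network <- function() {
  iso <- isoform_accessions()[c("beta", "gamma")]
  edges <- data.frame(
    id_a = c(iso[["beta"]], iso[["beta"]], iso[["gamma"]], iso[["gamma"]],
             "K0001"),
    id_b = c("P0001", "P0002", "P0002", "P0003", "P0001"),
    source = "toy", stringsAsFactors = FALSE)
  ann <- list(
    domains = data.frame(protein_id = c("P0001", "P0001", "P0002", "P0003"),
                         domain_name = c("SH3", "NLS", "RRM", "PDZ"),
                         start = c(10L, 150L, 20L, 5L),
                         end = c(100L, 159L, 90L, 80L),
                         stringsAsFactors = FALSE),
    disorder = data.frame(protein_id = c("P0001", "P0002", "P0003"),
                          start = c(110L, 100L, 90L),
                          end = c(140L, 180L, 200L),
                          stringsAsFactors = FALSE),
    go = data.frame(protein_id = character(0), term_id = character(0)),
    localization = data.frame(protein_id = c("P0001", "P0002", "P0003"),
                              label = c("nuclear", "cytoplasmic", "nuclear"),
                              stringsAsFactors = FALSE),
    kinase_groups = data.frame(protein_id = "K0001", group = "AGC",
                               stringsAsFactors = FALSE),
    clades = data.frame(protein_id = c("P0001", "P0002"),
                        clade_id = c(172L, 1100L), stringsAsFactors = FALSE))
  ptms <- validate_ptm_sites(data.frame(
    protein_id = c("P0001", "P0001", "P0001", "P0001", "P0002", "P0003"),
    position = c(120L, 125L, 130L, 50L, 30L, 95L),
    residue = c("S", "S", "S", "Y", "K", "T"),
    modification = c("phosphorylation", "phosphorylation", "phosphorylation",
                     "phosphorylation", "acetylation", "phosphorylation"),
    stringsAsFactors = FALSE))
  lengths <- data.frame(protein_id = c("P0001", "P0002", "P0003", "K0001",
                                       unname(iso)),
                        length = c(200L, 220L, 250L, 300L, 245L, 245L),
                        stringsAsFactors = FALSE)
  suppressWarnings(assemble_full_network(edges, ann, ptms,
                                         isoform_id_map = iso,
                                         lengths = lengths))
}

# scaled-down simulation used where full size is unnecessary
small_sim_config <- function(seed, ...) {
  sim_config(seed = seed, n_proteins = 400L, n_partners = 60L,
             background_edges = 80L, ...)
}
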