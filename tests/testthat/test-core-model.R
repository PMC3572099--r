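test_that("accession normalization strips isoform suffixes and is idempotent", {
  expect_equal(normalize_accession("p62258-2"), "P62258")
  expect_equal(normalize_accession("P31946"), "P31946")
  expect_equal(normalize_accession("  q04917 "), "Q04917")
  expect_error(normalize_accession(""), "malformed")
  set.seed(5)
  raw <- paste0(sample(c("p", "P", "q"), 50, TRUE),
                sample(10000:99999, 50),
                sample(c("", "-1", "-2", "-12"), 50, TRUE))
  once <- normalize_accession(raw)
  expect_identical(normalize_accession(once), once)
})

test_that("interaction reader deduplicates undirected pairs and reports rejects", {
  p <- write_tsv(data.frame(id_a = c("A1", "B1"), id_b = c("B1", "A1"),
                            source = "x"))
  e <- read_interactions(p)
  expect_equal(nrow(e), 1L)
  empty <- write_tsv(data.frame(id_a = character(0), id_b = character(0)))
  expect_equal(nrow(read_interactions(empty)), 0L)
  bad <- tempfile()
  writeLines(c("id_a\tid_b", "A1\tB1", "C1\t"), bad)
  e2 <- read_interactions(bad)
  expect_equal(nrow(e2), 1L)
  expect_equal(attr(e2, "rejects")$reason, "missing identifier")
  noid <- write_tsv(data.frame(id_a = "A1", other = "B1"))
  expect_error(read_interactions(noid), "id_b")
  # row order never matters
  p1 <- write_tsv(data.frame(id_a = c("A1", "C1", "B1"),
                             id_b = c("B1", "A1", "C1")))
  p2 <- write_tsv(data.frame(id_a = c("B1", "A1", "C1"),
                             id_b = c("C1", "B1", "A1")))
  expect_identical(read_interactions(p1)[, 1:2], read_interactions(p2)[, 1:2])
  # self-interactions dropped by default
  ps <- write_tsv(data.frame(id_a = c("A1", "A1"), id_b = c("A1", "B1")))
  expect_equal(nrow(read_interactions(ps)), 1L)
})

test_that("PTM reader enforces residue/modification compatibility", {
  p <- write_tsv(data.frame(protein_id = "P1", position = 15, residue = "S",
                            modification = "phosphorylation"))
  s <- read_ptm_table(p)
  expect_equal(nrow(s), 1L)
  expect_equal(s$position, 15L)
  dup <- write_tsv(data.frame(protein_id = c("P1", "P1"),
                              position = c(15, 15), residue = c("S", "S"),
                              modification = "phosphorylation"))
  expect_equal(nrow(read_ptm_table(dup)), 1L)
  bad <- write_tsv(data.frame(protein_id = c("P1", "P1", "P1"),
                              position = c("x", "10", "20"),
                              residue = c("S", "K", "S"),
                              modification = c("phosphorylation",
                                               "phosphorylation",
                                               "acetylation")))
  expect_warning(s2 <- read_ptm_table(bad), "3 PTM row")
  expect_equal(nrow(s2), 0L)
  expect_setequal(attr(s2, "rejects")$reason,
                  c("position not a positive integer",
                    "phosphorylation on non-S/T/Y residue",
                    "acetylation on non-K residue"))
})

test_that("annotation bundle merges overlapping disorder and tolerates absent files", {
  dpath <- write_tsv(data.frame(protein_id = c("P1", "P1"),
                                start = c(1, 5), end = c(10, 20)))
  ann <- read_annotation_tables(disorder_path = dpath)
  expect_equal(ann$disorder$start, 1L)
  expect_equal(ann$disorder$end, 20L)
  expect_equal(nrow(ann$localization), 0L)
  dom <- write_tsv(data.frame(protein_id = "P1", domain_name = "SH3",
                              start = 5, end = 60))
  ann2 <- read_annotation_tables(domain_path = dom)
  expect_equal(nrow(ann2$domains), 1L)
  cl <- write_tsv(data.frame(protein_id = c("P1", "P2"),
                             clade_id = c(100, 2000)))
  ann3 <- read_annotation_tables(clade_path = cl)
  expect_equal(nrow(ann3$clades), 1L)
  expect_match(attr(ann3, "log"), "clades", all = FALSE)
})

test_that("network assembly reports the documented counts", {
  net <- toy_network()
  s <- summary(net)
  expect_equal(s$n_nodes, 6L)   # 2 hubs + 3 partners + 1 kinase
  expect_equal(s$n_edges, 5L)
  expect_equal(s$n_clients, 3L)
  # duplicated interaction rows leave counts unchanged
  iso <- isoform_accessions()["beta"]
  edges <- data.frame(id_a = c(iso, iso, "K1"), id_b = c("A1", "A1", "A1"),
                      source = "x", stringsAsFactors = FALSE)
  net2 <- suppressWarnings(assemble_full_network(edges,
                                                 isoform_id_map = iso))
  expect_equal(summary(net2)$n_edges, 2L)
  # 1 isoform + 2 partners + 1 kinase edge -> 4 nodes, 3 edges
  edges3 <- data.frame(id_a = c(iso, iso, "K1"), id_b = c("A1", "B1", "A1"),
                       source = "x", stringsAsFactors = FALSE)
  s3 <- summary(assemble_full_network(edges3, isoform_id_map = iso))
  expect_equal(s3$n_nodes, 4L)
  expect_equal(s3$n_edges, 3L)
})

test_that("unknown lengths fall back to the largest annotated coordinate", {
  iso <- isoform_accessions()["beta"]
  edges <- data.frame(id_a = iso, id_b = "A1", source = "x",
                      stringsAsFactors = FALSE)
  ann <- read_annotation_tables()
  ann$domains <- data.frame(protein_id = "A1", domain_name = "SH3",
                            start = 10L, end = 90L)
  ptms <- validate_ptm_sites(data.frame(protein_id = "A1", position = 150L,
                                        residue = "S",
                                        modification = "phosphorylation"))
  net <- assemble_full_network(edges, ann, ptms, isoform_id_map = iso)
  expect_equal(net$proteins$length[net$proteins$protein_id == "A1"], 150L)
})

test_that("GraphML round trip reproduces nodes, edges and attributes", {
  net <- toy_network()
  path <- tempfile(fileext = ".graphml")
  write_network(net, path)
  back <- read_network(path)
  expect_setequal(back$proteins$protein_id, net$proteins$protein_id)
  expect_identical(back$edges[, c("id_a", "id_b")],
                   net$edges[, c("id_a", "id_b")])
  ord <- match(net$proteins$protein_id, back$proteins$protein_id)
  expect_identical(back$proteins$length[ord], net$proteins$length)
  expect_identical(back$proteins$is_kinase[ord], net$proteins$is_kinase)
  counts <- paralognet:::ptm_count_matrix(net)
  expect_identical(as.integer(back$proteins$n_pS[ord]),
                   unname(counts[net$proteins$protein_id, "pS"]))
  expect_identical(back$isoform_ids, net$isoform_ids)
  # empty network writes a valid document
  empty <- annotated_network(
    data.frame(protein_id = character(0), length = integer(0)),
    data.frame(id_a = character(0), id_b = character(0),
               source = character(0)),
    isoform_ids = character(0))
  p2 <- tempfile(fileext = ".graphml")
  write_network(empty, p2)
  expect_equal(nrow(read_network(p2)$proteins), 0L)
})

test_that("orientation posteriors survive the GraphML round trip to 6 decimals", {
  b <- simulate_cohort(small_sim_config(1))
  net <- bundle_network(b)
  dnet <- orient_network(net, train_edge_classifier(net, b$train),
                         curated = b$train)
  path <- tempfile(fileext = ".csv")
  write_network(dnet, path, format = "tsv")
  back <- utils::read.csv(path)
  expect_equal(back$posterior, dnet$edges$posterior, tolerance = 5e-7)
  expect_identical(back$direction, dnet$edges$direction)
})

test_that("loading identical files twice yields identical summaries", {
  b <- simulate_cohort(small_sim_config(4))
  d <- tempfile()
  generate_bundle(b, d)
  load_once <- function() {
    ann <- read_annotation_tables(
      domain_path = file.path(d, "domains.tsv"),
      disorder_path = file.path(d, "disorder.tsv"),
      go_path = file.path(d, "go.tsv"),
      localization_path = file.path(d, "localization.tsv"),
      kinase_group_path = file.path(d, "kinase_groups.tsv"),
      clade_path = file.path(d, "clades.tsv"))
    net <- assemble_full_network(
      read_interactions(file.path(d, "interactions.tsv")), ann,
      read_ptm_table(file.path(d, "ptm.tsv")),
      lengths = read.delim(file.path(d, "lengths.tsv")))
    net
  }
  n1 <- load_once(); n2 <- load_once()
  expect_identical(n1, n2)
})
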