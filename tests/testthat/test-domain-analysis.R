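test_that("domain frequencies count proteins, not instances, and honor exclusions", {
  iso <- isoform_accessions()["beta"]
  ids <- paste0("D", 1:4)
  edges <- data.frame(id_a = unname(iso), id_b = ids, source = "t",
                      stringsAsFactors = FALSE)
  ann <- read_annotation_tables()
  ann$domains <- data.frame(
    protein_id = c("D1", "D2", "D2", "D2", "D3"),
    domain_name = c("PDZ", "PDZ", "PDZ", "PDZ", "CC"),
    start = c(10L, 10L, 120L, 240L, 10L),
    end = c(100L, 100L, 200L, 300L, 60L))
  net <- assemble_full_network(edges, ann, isoform_id_map = iso,
                               lengths = data.frame(
                                 protein_id = c(ids, unname(iso)), length = 400L))
  p <- extract_paralog_subnetwork(net, "beta", include_kinase_layer = FALSE)
  prof <- domain_frequencies(p)
  expect_equal(prof$frequency[prof$domain_name == "PDZ"], 0.5)  # 2 of 4
  expect_equal(prof$n_proteins[prof$domain_name == "PDZ"], 2L)  # D2 counted once
  expect_equal(prof$n_instances[prof$domain_name == "PDZ"], 4L)
  expect_false("CC" %in% prof$domain_name)
  # invariance to duplicated annotation rows
  ann2 <- ann
  ann2$domains <- rbind(ann$domains, ann$domains)
  net2 <- assemble_full_network(edges, ann2, isoform_id_map = iso,
                                lengths = data.frame(
                                  protein_id = c(ids, unname(iso)), length = 400L))
  p2 <- extract_paralog_subnetwork(net2, "beta", include_kinase_layer = FALSE)
  expect_equal(domain_frequencies(p2)$frequency,
               prof$frequency[match(domain_frequencies(p2)$domain_name,
                                    prof$domain_name)])
})

test_that("top-n union is deterministic under ties", {
  mk <- function(doms, freq, n) {
    data.frame(isoform = "x", domain_name = doms, n_proteins = n,
               n_instances = n, frequency = freq, stringsAsFactors = FALSE)
  }
  one <- mk(c("A", "B", "C"), c(0.3, 0.2, 0.1), 3:1)
  expect_setequal(top_n_union(list(one), 10), c("A", "B", "C"))
  expect_equal(top_n_union(list(one, one), 2), c("A", "B"))
  tied <- mk(c("B", "A", "C"), c(0.3, 0.2, 0.2), c(3L, 2L, 2L))
  expect_equal(top_n_union(list(tied), 2), c("A", "B"))  # lexicographic tie
  expect_error(top_n_union(list(one), 0), ">= 1")
})

test_that("pairwise domain enrichment recovers the planted RRM excess", {
  b <- simulate_cohort(small_sim_config(16))
  net <- bundle_network(b)
  pn <- paralog_subnetworks(net)
  pm <- domain_enrichment_tests(pn, "RRM")
  expect_equal(pm, t(pm))
  row_min <- apply(pm, 1, min, na.rm = TRUE)
  expect_equal(names(which.min(row_min)), "gamma")
  # identical profiles -> p = 1
  two <- list(a = pn$beta, b = pn$beta)
  two$a$isoform <- "a"; two$b$isoform <- "b"
  expect_equal(unname(domain_enrichment_tests(two, "SH3")["a", "b"]), 1)
})

test_that("bipartite network edges are monotone in the significance cutoff", {
  b <- simulate_cohort(small_sim_config(17))
  net <- bundle_network(b)
  pn <- paralog_subnetworks(net)
  b01 <- build_bipartite(pn, alpha = 0.01)
  b05 <- build_bipartite(pn, alpha = 0.05)
  key <- function(bb) paste(bb$edges$domain, bb$edges$isoform)
  expect_true(all(key(b01) %in% key(b05)))
  expect_true(all(b01$edges$min_p <= 0.01))
  expect_true(all(b01$domain_degree >= 0))
  # no-signal case: identical networks yield no edges
  two <- list(a = pn$beta, b = pn$beta)
  two$a$isoform <- "a"; two$b$isoform <- "b"
  expect_equal(nrow(build_bipartite(two, alpha = 0.01)$edges), 0L)
})

test_that("modified-domain profiles require a matching site inside the domain", {
  iso <- isoform_accessions()["beta"]
  edges <- data.frame(id_a = unname(iso), id_b = c("M1", "M2"), source = "t",
                      stringsAsFactors = FALSE)
  ann <- read_annotation_tables()
  ann$domains <- data.frame(protein_id = c("M1", "M2"),
                            domain_name = c("Tyr_Kinase", "SH3"),
                            start = c(10L, 10L), end = c(300L, 60L))
  ptms <- validate_ptm_sites(data.frame(
    protein_id = c("M1", "M2"), position = c(50L, 200L),
    residue = c("Y", "S"),
    modification = "phosphorylation"))
  net <- assemble_full_network(edges, ann, ptms, isoform_id_map = iso,
                               lengths = data.frame(
                                 protein_id = c("M1", "M2", unname(iso)),
                                 length = 400L))
  p <- extract_paralog_subnetwork(net, "beta", include_kinase_layer = FALSE)
  prof <- modified_domain_frequencies(p, "phospho")
  expect_equal(prof$domain_name, "Tyr_Kinase")   # M2's pS at 200 is outside SH3
  expect_equal(prof$n_proteins, 1L)
  # containment: modified count never exceeds the domain-carrier count
  b <- simulate_cohort(small_sim_config(18))
  netb <- bundle_network(b)
  pz <- extract_paralog_subnetwork(netb, "zeta")
  all_dom <- domain_frequencies(pz, exclude = "CC")
  mod <- modified_domain_frequencies(pz, "acetyl", top_n = Inf)
  idx <- match(mod$domain_name, all_dom$domain_name)
  expect_true(all(mod$n_proteins <= all_dom$n_proteins[idx]))
})

test_that("clade profiles split social and isolated domains", {
  net <- toy_network()
  p <- extract_paralog_subnetwork(net, "beta", include_kinase_layer = FALSE)
  cp <- clade_profile(p)   # P0001 -> 172 (social), P0002 -> 1100 (isolated)
  expect_equal(sort(cp$profile$clade_id), c(172L, 1100L))
  expect_equal(cp$isolated_fraction, 0.5)
  expect_equal(cp$n_unmapped, 0L)
  empty <- clade_profile(p, clade_map = data.frame(protein_id = character(0),
                                                   clade_id = integer(0)))
  expect_equal(empty$n_unmapped, 2L)
  expect_true(is.na(empty$isolated_fraction))
  expect_warning(
    clade_profile(p, clade_map = data.frame(protein_id = "P0001",
                                            clade_id = 1300L)),
    "rejected")
})
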