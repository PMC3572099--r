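test_that("bundle generation is deterministic per seed", {
  b1 <- simulate_cohort(small_sim_config(23))
  b2 <- simulate_cohort(small_sim_config(23))
  expect_identical(b1$interactions, b2$interactions)
  expect_identical(b1$ptm, b2$ptm)
  expect_identical(b1$directions, b2$directions)
  d1 <- tempfile(); d2 <- tempfile()
  generate_bundle(b1, d1)
  generate_bundle(simulate_cohort(small_sim_config(23)), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  b3 <- simulate_cohort(small_sim_config(24))
  expect_false(identical(b1$ptm, b3$ptm))
})

test_that("partner-set overlap hits its Jaccard targets", {
  b <- simulate_cohort(small_sim_config(25))
  net <- bundle_network(b)
  jm <- jaccard_matrix(paralog_subnetworks(net))
  expect_lt(abs(jm["theta", "beta"] - 0.273), 0.05)
  off <- jm["beta", "gamma"]
  expect_lt(abs(off - 0.10), 0.05)
  # full overlap parameter: every pairwise Jaccard is 1
  full <- simulate_cohort(sim_config(seed = 1, n_proteins = 300L,
                                     n_partners = 40L, jaccard_base = 1,
                                     jaccard_pairs = list(),
                                     background_edges = 30L,
                                     planted_ffl = 10L))
  jf <- jaccard_matrix(paralog_subnetworks(bundle_network(full)))
  expect_true(all(abs(unclass(jf) - 1) < 1e-12))
  # infeasible demand errors with guidance
  expect_error(simulate_cohort(sim_config(seed = 1, n_proteins = 120L,
                                          n_partners = 110L)),
               "infeasible")
})

test_that("emitted files parse cleanly through the standard readers", {
  d <- tempfile()
  generate_bundle(small_sim_config(26), d)
  edges <- read_interactions(file.path(d, "interactions.tsv"))
  expect_gt(nrow(edges), 100)
  expect_equal(nrow(attr(edges, "rejects")), 0L)
  ptm <- read_ptm_table(file.path(d, "ptm.tsv"))
  expect_equal(nrow(attr(ptm, "rejects")), 0L)
  ann <- read_annotation_tables(
    domain_path = file.path(d, "domains.tsv"),
    disorder_path = file.path(d, "disorder.tsv"),
    go_path = file.path(d, "go.tsv"),
    localization_path = file.path(d, "localization.tsv"),
    kinase_group_path = file.path(d, "kinase_groups.tsv"),
    clade_path = file.path(d, "clades.tsv"))
  expect_gt(nrow(ann$domains), 100)
  dag <- read_obo(file.path(d, "go.obo"))
  expect_equal(nrow(dag$terms), 60L)
  net <- assemble_full_network(edges, ann, ptm,
                               lengths = read.delim(file.path(d,
                                                              "lengths.tsv")))
  expect_equal(summary(net)$n_edges, nrow(edges))
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_equal(length(truth$partner_sets), 7L)
})

test_that("planted structures are consistent with the emitted files", {
  b <- simulate_cohort(small_sim_config(27, planted_ffl = 15L))
  ekey <- paste(b$interactions$id_a, b$interactions$id_b)
  tri <- b$truth$planted_ffls
  ffl_edges <- rbind(cbind(tri$x, tri$y), cbind(tri$x, tri$z),
                     cbind(tri$y, tri$z))
  expect_true(all(paste(pmin(ffl_edges[, 1], ffl_edges[, 2]),
                        pmax(ffl_edges[, 1], ffl_edges[, 2])) %in% ekey))
  # every interaction has exactly one truth direction
  dkey <- paste(pmin(b$directions$from, b$directions$to),
                pmax(b$directions$from, b$directions$to))
  expect_setequal(dkey, paste(b$interactions$id_a, b$interactions$id_b))
  # curated training edges point kinase -> substrate
  expect_true(all(b$train$from %in% b$truth$kinase_ids))
  # site regions in the truth match the classifier on the assembled network
  net <- bundle_network(b)
  s <- b$truth$site_regions
  s <- s[s$protein_id %in% net$proteins$protein_id, , drop = FALSE]
  set.seed(1)
  idx <- sample(nrow(s), 200)
  got <- paralognet:::site_regions(net, s[idx, ])
  expect_equal(got, s$region[idx])
})

test_that("realized site densities converge to the configured rates", {
  cfg <- sim_config(seed = 28, n_proteins = 5000L, n_partners = 120L,
                    planted_ffl = 0L)
  b <- simulate_cohort(null_config(cfg))
  s <- b$truth$site_regions
  # exact region residue totals, reconstructed by interval expansion with
  # the same precedence rule (domain over disordered)
  lengths <- b$proteins$length[match(sprintf("SYN%05d", 1:5000),
                                     b$proteins$protein_id)]
  ids <- sprintf("SYN%05d", 1:5000)
  off <- c(0L, cumsum(lengths))
  region <- rep.int(1L, off[length(off)])
  expand <- function(tab, code) {
    w <- tab$end - tab$start + 1L
    gidx <- sequence(nvec = w, from = off[match(tab$protein_id, ids)] +
                       tab$start)
    region[gidx] <<- code
  }
  expand(b$disorder, 2L)
  expand(b$domains, 3L)
  reg_res <- c(other = sum(region == 1L), disordered = sum(region == 2L),
               domain = sum(region == 3L))
  rates <- default_ptm_rates()
  for (chk in list(c("disordered", "S", "pS"), c("domain", "K", "acK"),
                   c("domain", "Y", "pY"), c("other", "T", "pT"))) {
    n_sites <- sum(s$region == chk[1] &
                     b$ptm$residue[match(paste(s$protein_id, s$position),
                                         paste(b$ptm$protein_id,
                                               b$ptm$position))] == chk[2])
    realized <- n_sites / reg_res[chk[1]]
    expect_lt(abs(realized - rates[chk[1], chk[3]]) / rates[chk[1], chk[3]],
              0.1)
  }
})

test_that("null bundles carry no planted effects", {
  cfg <- null_config(small_sim_config(29))
  expect_equal(cfg$mult_zeta_acK, 1)
  expect_equal(cfg$planted_ffl, 0L)
  b <- simulate_cohort(cfg)
  expect_null(b$truth$planted_ffls)
  expect_equal(b$truth$multipliers$epsilon_pY_domain, 1)
})
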