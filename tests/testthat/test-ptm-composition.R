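test_that("residue positions classify with domain-over-disorder precedence", {
  net <- toy_network()
  # P0001: domain SH3 10-100, NLS 150-159; disorder 110-140
  expect_equal(classify_position(net, "P0001", 50), "domain")
  expect_equal(classify_position(net, "P0001", 120), "disordered")
  expect_equal(classify_position(net, "P0001", 145), "other")
  expect_error(classify_position(net, "P0001", 0), "out of range")
  expect_error(classify_position(net, "P0001", 999), "out of range")
  # P0003: domain 5-80, disorder 90-200: overlap region decided by precedence
  over <- annotated_network(
    data.frame(protein_id = "X1", length = 100L),
    data.frame(id_a = character(0), id_b = character(0),
               source = character(0)),
    isoform_ids = character(0),
    domains = data.frame(protein_id = "X1", domain_name = "SH3",
                         start = 10L, end = 60L),
    disorder = data.frame(protein_id = "X1", start = 40L, end = 90L))
  expect_equal(classify_position(over, "X1", 50), "domain")
  expect_equal(classify_position(over, "X1", 50, precedence = "disordered"),
               "disordered")
})

test_that("composition table assigns each site to exactly one cell", {
  net <- toy_network()
  p <- extract_paralog_subnetwork(net, "beta", include_kinase_layer = FALSE)
  ct <- as.data.frame(composition_table(p))
  # beta partners: P0001 (3 pS disordered, 1 pY domain), P0002 (1 acK domain)
  get <- function(region, cls) ct$count[ct$region == region & ct$class == cls]
  expect_equal(get("disordered", "pS"), 3L)
  expect_equal(get("domain", "pY"), 1L)
  expect_equal(get("domain", "acK"), 1L)
  expect_equal(ct$percent[ct$region == "disordered" & ct$class == "pS"], 100)
  expect_equal(ct$percent[ct$region == "domain" & ct$class == "pY"], 100)
  # totals row equals column sums over the three regions
  for (cls in c("pS", "pT", "pY", "acK"))
    expect_equal(get("total", cls),
                 sum(get("domain", cls), get("disordered", cls),
                     get("other", cls)))
})

test_that("site totals are conserved across region stratification", {
  b <- simulate_cohort(small_sim_config(12))
  net <- bundle_network(b)
  for (l in c("beta", "zeta")) {
    p <- extract_paralog_subnetwork(net, l)
    ct <- as.data.frame(composition_table(p))
    cm <- paralognet:::ptm_count_matrix(net)
    expect_equal(sum(ct$count[ct$region != "total"]),
                 sum(cm[p$partner_ids, ]))
    # per-region phospho percentages sum to 100
    for (r in c("domain", "disordered", "other")) {
      tot <- sum(ct$count[ct$region == r & ct$class %in% c("pS", "pT", "pY")])
      if (tot > 0)
        expect_equal(sum(ct$percent[ct$region == r &
                                      ct$class %in% c("pS", "pT", "pY")]),
                     100, tolerance = 0.5)
    }
  }
})

test_that("fraction comparison: identity gives p = 1, zero denominator errors", {
  b <- simulate_cohort(small_sim_config(13))
  net <- bundle_network(b)
  pn <- paralog_subnetworks(net)
  same <- compare_fraction(pn$beta, pn$beta, counter_pY_in_domain)
  expect_equal(same$p, 1)
  empty_counter <- function(p) c(0, 0)
  expect_error(compare_fraction(pn$beta, pn$gamma, empty_counter),
               "zero denominator")
})

test_that("acetylation burden satisfies containment and symmetry", {
  b <- simulate_cohort(small_sim_config(14))
  net <- bundle_network(b)
  pn <- paralog_subnetworks(net)
  ab <- acetylation_burden(pn)
  expect_true(all(ab$counts$acK_in_domain <= ab$counts$acK_sites))
  expect_true(all(ab$counts$acetylated_partners <= ab$counts$partners))
  expect_equal(ab$p_matrix, t(ab$p_matrix))
  q <- attr(ab, "q_matrix")
  expect_true(all(q[upper.tri(q)] >= ab$p_matrix[upper.tri(q)] - 1e-12))
  # identical partner sets give p = 1 on every pair
  two <- list(a = pn$beta, b = pn$beta)
  two$b$isoform <- "b"; two$a$isoform <- "a"
  ab2 <- acetylation_burden(two)
  expect_equal(ab2$p_matrix["a", "b"], 1)
})

test_that("crosstalk association matches the exact-test oracle and flags degeneracy", {
  prof_net <- function(ptms) {
    ids <- unique(ptms$protein_id)
    iso <- isoform_accessions()["beta"]
    edges <- data.frame(id_a = unname(iso), id_b = ids, source = "t",
                        stringsAsFactors = FALSE)
    ann <- read_annotation_tables()
    net <- assemble_full_network(edges, ann, validate_ptm_sites(ptms),
                                 isoform_id_map = iso,
                                 lengths = data.frame(protein_id = c(ids, unname(iso)),
                                                      length = 500L))
    extract_paralog_subnetwork(net, "beta", include_kinase_layer = FALSE)
  }
  # perfect coupling: 4 partners with both pY and acK, 4 with neither PTM
  ptms <- rbind(
    data.frame(protein_id = paste0("A", 1:4), position = 10L, residue = "Y",
               modification = "phosphorylation"),
    data.frame(protein_id = paste0("A", 1:4), position = 20L, residue = "K",
               modification = "acetylation"),
    data.frame(protein_id = paste0("B", 1:4), position = 30L, residue = "S",
               modification = "phosphorylation"))
  res <- crosstalk_association(prof_net(ptms), "Y")
  expect_equal(res$table[1, 1], 4L)
  expect_equal(res$p, fisher_oracle(4, 0, 0, 4), tolerance = 1e-12)
  # no acetylation anywhere: degenerate, p = 1
  res2 <- crosstalk_association(prof_net(ptms[ptms$modification !=
                                                "acetylation", ]), "Y")
  expect_true(res2$degenerate)
  expect_equal(res2$p, 1)
})

test_that("proportionality fit reproduces closed-form least squares", {
  f <- proportionality_fit(1:5, 2 * (1:5))
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_equal(proportionality_fit(1:5, rep(3, 5))$r_squared, 0,
               tolerance = 1e-12)
  x <- c(1, 2, 4, 7); y <- c(2.1, 3.9, 8.3, 13.8)
  f2 <- proportionality_fit(x, y)
  # closed-form OLS recomputed here
  bhat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ahat <- mean(y) - bhat * mean(x)
  r2 <- 1 - sum((y - ahat - bhat * x)^2) / sum((y - mean(y))^2)
  expect_equal(f2$slope, bhat, tolerance = 1e-9)
  expect_equal(f2$intercept, ahat, tolerance = 1e-9)
  expect_equal(f2$r_squared, r2, tolerance = 1e-9)
  expect_error(proportionality_fit(rep(1, 4), 1:4), "zero variance")
  expect_error(proportionality_fit(1:2, 1:2), ">= 3")
})

test_that("kinase group profile normalizes rows and flags empty networks", {
  net <- toy_network()
  pn <- paralog_subnetworks(net)   # kinase K0001 (AGC) adjacent to P0001
  prof <- kinase_group_profile(pn)
  expect_equal(unname(prof["beta", "AGC"]), 1)
  expect_equal(sum(prof["beta", ]), 1)
  # gamma's partners have no adjacent kinase -> zero row, flagged
  expect_equal(sum(prof["gamma", ]), 0)
  expect_true("gamma" %in% attr(prof, "zero_rows"))
})

test_that("localization statistics quantify NLS concentration", {
  net <- toy_network()
  p <- extract_paralog_subnetwork(net, "beta", include_kinase_layer = FALSE)
  all_in <- localization_stats(p, function(prof) rep(TRUE, nrow(prof)))
  expect_true(all_in$degenerate)
  expect_equal(unname(all_in$fractions["subset_share"]), 1)
  expect_equal(unname(all_in$fractions["nls_share"]), 1)
  none <- localization_stats(p, function(prof) rep(FALSE, nrow(prof)))
  expect_true(none$degenerate)
  sub <- localization_stats(p, "P0001")   # the NLS carrier
  expect_equal(unname(sub$fractions["nls_share"]), 1)
  expect_equal(sum(sub$table), 2L)
  # missing localization table is an instructive error
  bare <- annotated_network(net$proteins, net$edges, net$isoform_ids,
                            domains = net$domains, disorder = net$disorder,
                            ptms = net$ptms)
  pb <- extract_paralog_subnetwork(bare, "beta", include_kinase_layer = FALSE)
  expect_error(localization_stats(pb, "P0001"), "localization")
})

test_that("the acetylation-localization coupling is detected at the stated effect", {
  b <- simulate_cohort(small_sim_config(15))
  net <- bundle_network(b)
  pn <- paralog_subnetworks(net)
  all_clients <- pooled_partners(pn, exclude = character(0))
  res <- localization_stats(all_clients, function(prof) prof$n_acK > 0)
  expect_false(res$degenerate)
  expect_lt(res$p, 0.05)
  # NLS content concentrates in the acetylated subset
  prof <- partner_profile(all_clients)
  expect_gt(mean(prof$has_nls[prof$n_acK > 0]),
            mean(prof$has_nls[prof$n_acK == 0]))
})

test_that("disorder comparison reports all three test families", {
  b <- simulate_cohort(small_sim_config(15))
  net <- bundle_network(b)
  pn <- paralog_subnetworks(net)
  dc <- compare_disorder_content(pn)
  expect_true(dc$kruskal$p >= 0 && dc$kruskal$p <= 1)
  expect_equal(dc$wilcoxon_p, t(dc$wilcoxon_p))
  expect_equal(dc$fisher_p, t(dc$fisher_p))
  expect_true(all(dc$fisher_p[upper.tri(dc$fisher_p)] > 0))
})
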