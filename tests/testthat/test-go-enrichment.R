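toy_obo <- function() {
  path <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root process",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: mid A",
    "namespace: biological_process", "is_a: GO:0000001 ! root process", "",
    "[Term]", "id: GO:0000003", "name: mid B",
    "namespace: biological_process", "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000004", "name: leaf diamond",
    "namespace: biological_process", "is_a: GO:0000002", "is_a: GO:0000003",
    "",
    "[Term]", "id: GO:0000009", "name: gone",
    "namespace: biological_process", "is_obsolete: true", ""), path)
  path
}

test_that("OBO parsing keeps is_a structure and drops obsolete terms", {
  dag <- read_obo(toy_obo())
  expect_equal(nrow(dag$terms), 4L)
  expect_equal(dag$n_obsolete, 1L)
  expect_setequal(dag$parents[["GO:0000004"]], c("GO:0000002", "GO:0000003"))
  expect_equal(dag$terms$namespace[1], "biological_process")
})

test_that("true-path propagation uses set semantics on diamond DAGs", {
  dag <- read_obo(toy_obo())
  ann <- data.frame(protein_id = c("P1", "P2"),
                    term_id = c("GO:0000004", "GO:0000001"))
  full <- propagate_annotations(ann, dag)
  p1 <- full$term_id[full$protein_id == "P1"]
  expect_setequal(p1, c("GO:0000001", "GO:0000002", "GO:0000003",
                        "GO:0000004"))
  expect_equal(sum(p1 == "GO:0000001"), 1L)  # diamond ancestor counted once
  # root annotation gains nothing
  expect_equal(full$term_id[full$protein_id == "P2"], "GO:0000001")
  # unknown terms are kept as direct-only and logged
  ann2 <- rbind(ann, data.frame(protein_id = "P3", term_id = "GO:9999999"))
  full2 <- propagate_annotations(ann2, dag)
  expect_equal(attr(full2, "n_unknown_terms"), 1L)
  expect_true("GO:9999999" %in% full2$term_id)
  # monotone counts: K(parent) >= K(child) for every is_a edge
  K <- table(full$term_id)
  for (child in names(dag$parents))
    for (par in dag$parents[[child]])
      expect_gte(K[par], K[child])
})

test_that("hypergeometric enrichment matches brute-force tail sums", {
  dag <- read_obo(toy_obo())
  set.seed(51)
  for (i in 1:20) {
    N <- sample(8:25, 1)
    universe <- paste0("U", 1:N)
    ann <- data.frame(
      protein_id = sample(universe, sample(3:N, 1), replace = FALSE),
      term_id = "GO:0000004")
    query <- sample(universe, sample(2:N, 1))
    res <- enrich(query, universe, ann, dag)
    row <- res[res$term_id == "GO:0000004", ]
    expect_equal(row$p, hyper_tail_oracle(row$k, row$n, row$K, row$N),
                 tolerance = 1e-9)
  }
  # query = universe: every p = 1
  ann <- data.frame(protein_id = c("U1", "U2"), term_id = "GO:0000004")
  res <- enrich(paste0("U", 1:5), paste0("U", 1:5), ann, dag)
  expect_true(all(res$p == 1))
  # term annotating exactly the query
  res2 <- enrich(c("U1", "U2"), paste0("U", 1:6), ann, dag)
  row <- res2[res2$term_id == "GO:0000004", ]
  expect_equal(row$p, hyper_tail_oracle(2, 2, 2, 6), tolerance = 1e-12)
  expect_error(enrich(character(0), paste0("U", 1:5), ann, dag), "empty")
  expect_error(enrich("Z9", paste0("U", 1:5), ann, dag), "subset")
  # BH q monotone in p rank
  expect_true(all(diff(res2$q[order(res2$p)]) >= -1e-12))
})

test_that("the planted GO boost is top-ranked for its isoform", {
  b <- simulate_cohort(small_sim_config(19))
  net <- bundle_network(b)
  pn <- paralog_subnetworks(net)
  res <- enrich(pn$gamma$partner_ids, net$proteins$protein_id, net$go,
                b$dag, "biological_process")
  expect_equal(res$term_id[1], b$truth$boost_term)
  expect_lt(res$p[1], 1e-4)
})

test_that("adaptive thresholding hits the target window when achievable", {
  mk <- function(p) {
    out <- data.frame(term_id = paste0("T", seq_along(p)),
                      name = "t", namespace = "bp", k = 1L, n = 1L, K = 1L,
                      N = 2L, p = p, q = p)
    class(out) <- c("enrichment_result", class(out))
    out
  }
  all40 <- adaptive_threshold(mk(rep(0.001, 40)))
  expect_equal(all40$achieved, 40L)
  expect_warning(few <- adaptive_threshold(mk(runif(10))), "nearest")
  expect_equal(few$achieved, 10L)
  set.seed(3)
  many <- adaptive_threshold(mk(sort(runif(100))))
  expect_true(many$achieved >= 35 && many$achieved <= 50)
  expect_error(adaptive_threshold(mk(0.5), lo = 5, hi = 2), "lo")
})

test_that("cross-isoform comparison flags untested and non-significant cells", {
  mk <- function(p, terms) {
    out <- data.frame(term_id = terms, name = "t", namespace = "bp",
                      k = 1L, n = 1L, K = 1L, N = 2L, p = p, q = p)
    class(out) <- c("enrichment_result", class(out))
    out
  }
  res <- list(a = mk(c(0.05, 0.001), c("T1", "T2")),
              b = mk(0.2, "T1"))
  cmp <- compare_enrichment(res, c("T1", "T2", "T3"))
  expect_equal(unname(cmp$neg_log10_p["a", "T2"]), -log10(0.001),
               tolerance = 1e-9)
  # p exactly at alpha is not significant; -log10(0.05) ~ 1.301 when below
  expect_equal(unname(cmp$neg_log10_p["a", "T1"]), 0)
  expect_equal(unname(cmp$status["a", "T1"]), "not_significant")
  expect_equal(unname(cmp$status["b", "T2"]), "untested")
  expect_equal(unname(cmp$neg_log10_p["b", "T3"]), 0)
  cmp2 <- compare_enrichment(list(a = res$a, b = res$a), c("T1", "T2"))
  expect_equal(cmp2$neg_log10_p["a", ], cmp2$neg_log10_p["b", ])
})
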