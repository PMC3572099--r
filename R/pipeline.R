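# End-to-end driver chaining the stages: simulate -> build -> orient ->
# motifs -> ptm -> domains -> enrich -> report. All results are plain CSV/
# JSON; identical configuration and seed reproduce identical files. A run
# manifest records the configuration hash and per-stage output hashes, and
# up-to-date stages are skipped on rerun.

#' Default pipeline configuration
#'
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @param out_dir Output directory.
#' @param sim Named list of overrides passed to [sim_config()].
#' @param ensemble_size Randomized ensemble size for the motif stage
#'   (default 200 here; [motif_significance()] itself defaults to 1000).
#' @param top_n_domains,alpha_domains Heat-map depth and bipartite cutoff.
#' @param alpha_go Significance threshold for the GO comparison.
#' @return Named list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = "results/pipeline",
                            sim = list(), ensemble_size = 200L,
                            top_n_domains = 10L, alpha_domains = 0.01,
                            alpha_go = 0.05) {
  list(seed = seed, out_dir = out_dir, sim = sim,
       ensemble_size = ensemble_size, top_n_domains = top_n_domains,
       alpha_domains = alpha_domains, alpha_go = alpha_go)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

write_result <- function(df, dir, name) {
  p <- file.path(dir, name)
  utils::write.csv(df, p, row.names = FALSE)
  p
}

#' Run the full comparative pipeline
#'
#' Generates (or reuses) a synthetic input bundle, reads it back through the
#' standard file readers, assembles and orients the network, and writes the
#' comparative result tables: network summary, Jaccard matrix, per-isoform
#' motif significance, PTM composition, acetylation burden, crosstalk,
#' disorder comparison, kinase-group profile, domain frequencies and
#' bipartite edges, modified-domain profiles, clade profiles, and GO
#' comparison; plus `manifest.json`.
#'
#' @param config From [pipeline_config()].
#' @param force Rerun every stage even if up to date (default FALSE).
#' @return List with `outputs` (named file paths), `manifest`, `skipped`.
#' @export
run_pipeline <- function(config = pipeline_config(), force = FALSE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  chash <- config_hash(config)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  old_manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else NULL
  reusable <- !force && !is.null(old_manifest) &&
    identical(old_manifest$config_hash, chash)
  up_to_date <- function(paths) {
    reusable && all(file.exists(unlist(paths))) &&
      identical(unname(tools::md5sum(unlist(paths))),
                unlist(old_manifest$hashes[basename(unlist(paths))],
                       use.names = FALSE))
  }
  outputs <- list()
  skipped <- character(0)

  # -- simulate -------------------------------------------------------------
  input_dir <- file.path(config$out_dir, "input")
  sim_cfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
  bundle <- generate_bundle(sim_cfg, input_dir)
  paths <- attr(bundle, "paths")

  # -- build ----------------------------------------------------------------
  ann <- read_annotation_tables(domain_path = paths[["domains"]],
                                disorder_path = paths[["disorder"]],
                                go_path = paths[["go"]],
                                localization_path = paths[["localization"]],
                                kinase_group_path = paths[["kinase_groups"]],
                                clade_path = paths[["clades"]])
  lengths <- read_table_checked(paths[["lengths"]], c("protein_id", "length"))
  net <- assemble_full_network(read_interactions(paths[["interactions"]]),
                               ann, read_ptm_table(paths[["ptm"]]),
                               lengths = lengths)
  s <- summary(net)
  pnets <- paralog_subnetworks(net)
  jm <- jaccard_matrix(pnets)
  outputs$summary <- write_result(
    data.frame(nodes = s$n_nodes, edges = s$n_edges, clients = s$n_clients),
    config$out_dir, "network_summary.csv")
  outputs$jaccard <- write_result(
    data.frame(isoform = rownames(jm), round(unclass(jm), 6)),
    config$out_dir, "jaccard.csv")
  outputs$network <- file.path(config$out_dir, "network.graphml")
  write_network(net, outputs$network)

  # -- orient ---------------------------------------------------------------
  train <- read_table_checked(paths[["train"]], c("from", "to"))
  model <- train_edge_classifier(net, train)
  dnet <- orient_network(net, model, curated = train)
  outputs$directed <- write_result(
    cbind(directed_edgelist(dnet),
          posterior = round(dnet$edges$posterior, 6),
          curated = dnet$edges$curated),
    config$out_dir, "directed_edges.csv")

  # -- motifs (per paralog directed subnetwork) -----------------------------
  motif_path <- file.path(config$out_dir, "motifs.csv")
  if (up_to_date(motif_path)) {
    skipped <- c(skipped, "motifs")
    outputs$motifs <- motif_path
  } else {
    del <- directed_edgelist(dnet)
    ekey <- paste(pmin(del$from, del$to), pmax(del$from, del$to), sep = "\r")
    motif_rows <- lapply(names(pnets), function(l) {
      p <- pnets[[l]]
      sub_key <- paste(p$edges$id_a, p$edges$id_b, sep = "\r")
      sub <- del[ekey %in% sub_key, , drop = FALSE]
      hubs <- unname(ISOFORM_ACCESSIONS)
      sub <- sub[!(sub$from %in% hubs | sub$to %in% hubs), , drop = FALSE]
      if (nrow(sub) < 5L) return(NULL)
      ms <- motif_significance(sub, ensemble_size = config$ensemble_size,
                               seed = config$seed + 100L + match(l, names(pnets)))
      cbind(isoform = l, as.data.frame(ms))
    })
    outputs$motifs <- write_result(do.call(rbind, motif_rows),
                                   config$out_dir, "motifs.csv")
  }

  # -- ptm ------------------------------------------------------------------
  comp <- do.call(rbind, lapply(pnets, function(p)
    as.data.frame(composition_table(p))))
  outputs$composition <- write_result(comp, config$out_dir, "composition.csv")
  burden <- acetylation_burden(pnets)
  outputs$burden <- write_result(burden$counts, config$out_dir, "burden.csv")
  outputs$burden_p <- write_result(
    data.frame(isoform = rownames(burden$p_matrix),
               round(burden$p_matrix, 8)),
    config$out_dir, "burden_pvalues.csv")
  ct <- do.call(rbind, lapply(names(pnets), function(l)
    do.call(rbind, lapply(c("S", "T", "Y"), function(r) {
      res <- crosstalk_association(pnets[[l]], r)
      data.frame(isoform = l, residue = r, p = res$p,
                 degenerate = res$degenerate)
    }))))
  outputs$crosstalk <- write_result(ct, config$out_dir, "crosstalk.csv")
  bubbles <- do.call(rbind, lapply(names(pnets), function(l) {
    prof <- partner_profile(pnets[[l]])
    agg <- stats::aggregate(list(n_proteins = prof$protein_id),
                            by = list(phospho = prof$n_pS + prof$n_pT +
                                        prof$n_pY, acetyl = prof$n_acK),
                            FUN = length)
    cbind(isoform = l, agg)
  }))
  outputs$bubbles <- write_result(bubbles, config$out_dir,
                                  "crosstalk_bubbles.csv")
  dis <- compare_disorder_content(pnets)
  outputs$disorder <- write_result(
    data.frame(isoform = rownames(dis$wilcoxon_p),
               round(dis$wilcoxon_p, 8)),
    config$out_dir, "disorder_wilcoxon.csv")
  kg <- kinase_group_profile(pnets)
  outputs$kinase_groups <- write_result(
    data.frame(isoform = rownames(kg), round(unclass(kg), 6)),
    config$out_dir, "kinase_groups.csv")
  loc <- localization_stats(pnets$zeta, function(prof) prof$n_acK > 0)
  outputs$localization <- write_result(
    data.frame(isoform = "zeta", t(round(loc$fractions, 6)),
               p_nls = loc$p),
    config$out_dir, "localization.csv")

  # -- domains --------------------------------------------------------------
  freqs <- do.call(rbind, lapply(pnets, domain_frequencies))
  outputs$domain_freq <- write_result(freqs, config$out_dir,
                                      "domain_frequencies.csv")
  bip <- build_bipartite(pnets, top_n = config$top_n_domains,
                         alpha = config$alpha_domains)
  outputs$bipartite <- write_result(bip$edges, config$out_dir,
                                    "domain_bipartite.csv")
  outputs$phospho_dom <- write_result(
    do.call(rbind, lapply(pnets, modified_domain_frequencies,
                          modification = "phospho")),
    config$out_dir, "phospho_domains.csv")
  outputs$acetyl_dom <- write_result(
    do.call(rbind, lapply(pnets, modified_domain_frequencies,
                          modification = "acetyl")),
    config$out_dir, "acetyl_domains.csv")
  cl <- do.call(rbind, lapply(names(pnets), function(l) {
    cp <- clade_profile(pnets[[l]])
    data.frame(isoform = l, n_unmapped = cp$n_unmapped,
               isolated_fraction = cp$isolated_fraction)
  }))
  outputs$clades <- write_result(cl, config$out_dir, "clades.csv")

  # -- enrich ---------------------------------------------------------------
  dag <- read_obo(paths[["obo"]])
  universe <- net$proteins$protein_id
  enr <- lapply(pnets, function(p)
    enrich(p$partner_ids, universe, net$go, dag, "biological_process"))
  terms <- unique(unlist(lapply(enr, function(e)
    utils::head(e$term_id[e$p < config$alpha_go], 10))))
  cmp <- compare_enrichment(enr, terms, config$alpha_go)
  outputs$go <- write_result(
    data.frame(isoform = rownames(cmp$neg_log10_p),
               round(cmp$neg_log10_p, 6), check.names = FALSE),
    config$out_dir, "go_comparison.csv")
  outputs$go_full <- write_result(
    do.call(rbind, lapply(names(enr), function(l)
      cbind(isoform = l, as.data.frame(enr[[l]])))),
    config$out_dir, "go_enrichment.csv")

  # -- manifest -------------------------------------------------------------
  files <- unlist(outputs)
  manifest <- list(config = config, config_hash = chash,
                   seed = config$seed,
                   input_hashes = as.list(tools::md5sum(unname(paths))),
                   hashes = as.list(tools::md5sum(unname(files))),
                   skipped = skipped)
  names(manifest$hashes) <- basename(unname(files))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  list(outputs = outputs, manifest = manifest, skipped = skipped)
}
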