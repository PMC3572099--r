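# Domain frequency profiles, pairwise enrichment, the significant
# domain-isoform bipartite network, modified-domain profiles, and clade
# ("domain club") profiles.

#' Domain frequency profile of one paralog network
#'
#' Counting unit is protein-level presence: a partner carrying any number of
#' copies of a domain counts once (the Fisher contrasts need per-protein
#' binary states); instance counts are retained for totals. Coiled-coil (CC)
#' and transmembrane (TM) annotations are super-numerary in every network and
#' excluded by default.
#'
#' @param pnet A `paralog_network`.
#' @param exclude Domain names to omit (default `c("CC", "TM")`).
#' @return data.frame (`isoform`, `domain_name`, `n_proteins`, `n_instances`,
#'   `frequency`) sorted by decreasing frequency; attribute `n_partners`.
#' @export
domain_frequencies <- function(pnet, exclude = c("CC", "TM")) {
  net <- pnet$net
  dom <- net$domains[net$domains$protein_id %in% pnet$partner_ids &
                       !net$domains$domain_name %in% exclude, , drop = FALSE]
  n_part <- length(pnet$partner_ids)
  if (nrow(dom) == 0L) {
    out <- data.frame(isoform = character(0), domain_name = character(0),
                      n_proteins = integer(0), n_instances = integer(0),
                      frequency = numeric(0))
  } else {
    inst <- table(dom$domain_name)
    prot <- table(unique(dom[, c("protein_id", "domain_name")])$domain_name)
    out <- data.frame(isoform = pnet$isoform, domain_name = names(prot),
                      n_proteins = as.integer(prot),
                      n_instances = as.integer(inst[names(prot)]),
                      frequency = as.integer(prot) / n_part,
                      stringsAsFactors = FALSE)
    out <- out[order(-out$frequency, -out$n_proteins, out$domain_name), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_partners") <- n_part
  out
}

#' Union of each profile's top-n domains
#'
#' Ties at rank n are broken by higher protein count, then lexicographically.
#'
#' @param profiles List of profiles from [domain_frequencies()].
#' @param n Top-n per profile (default 10).
#' @return Character vector of domain names (sorted union of the per-profile
#'   top lists).
#' @export
top_n_union <- function(profiles, n = 10) {
  if (n < 1) stop("n must be >= 1")
  if (length(profiles) == 0L) stop("need at least one profile")
  tops <- lapply(profiles, function(pr) {
    pr <- pr[order(-pr$frequency, -pr$n_proteins, pr$domain_name), ,
             drop = FALSE]
    utils::head(pr$domain_name, n)
  })
  sort(unique(unlist(tops)))
}

#' Pairwise Fisher enrichment of one domain across paralog networks
#'
#' For every unordered pair of networks, the 2x2 table (network x partner
#' carries the domain or not) and its two-sided Fisher p.
#'
#' @param pnets Named list of `paralog_network`s.
#' @param domain Domain name.
#' @param exclude Domains excluded from profiles (for consistency of
#'   carrier sets; default `c("CC", "TM")`).
#' @return Symmetric matrix of p-values.
#' @export
domain_enrichment_tests <- function(pnets, domain, exclude = c("CC", "TM")) {
  labs <- names(pnets)
  carriers <- lapply(pnets, function(p) {
    dom <- p$net$domains
    ids <- unique(dom$protein_id[dom$domain_name == domain &
                                   !dom$domain_name %in% exclude])
    c(with_dom = length(intersect(p$partner_ids, ids)),
      total = length(p$partner_ids))
  })
  k <- length(labs)
  pm <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    a <- carriers[[i]]; b <- carriers[[j]]
    pm[i, j] <- pm[j, i] <- fisher_exact(matrix(
      c(a[1], a[2] - a[1], b[1], b[2] - b[1]), 2, byrow = TRUE))$p
  }
  pm
}

#' Significant domain-isoform bipartite network
#'
#' For every domain in the top-n union, a domain-isoform edge is drawn when
#' that isoform differs significantly (two-sided Fisher, p <= alpha) from at
#' least one other isoform for that domain; the edge sign records whether the
#' isoform's carrier frequency is above (presence) or below (absence) the
#' comparison partner's.
#'
#' @param pnets Named list of `paralog_network`s.
#' @param top_n Top-n per profile feeding the union (default 10).
#' @param alpha Significance cutoff (default 0.01).
#' @param exclude Domains to omit.
#' @return List of class `domain_isoform_bipartite`: `edges` (data.frame
#'   `domain`, `isoform`, `sign`, `min_p`), `domains`, `isoforms`,
#'   `domain_degree` (isoforms linked per domain), `alpha`.
#' @export
build_bipartite <- function(pnets, top_n = 10, alpha = 0.01,
                            exclude = c("CC", "TM")) {
  labs <- names(pnets)
  profiles <- lapply(pnets, domain_frequencies, exclude = exclude)
  doms <- top_n_union(profiles, top_n)
  freq_of <- function(pr, d) {
    i <- match(d, pr$domain_name)
    if (is.na(i)) 0 else pr$frequency[i]
  }
  edges <- NULL
  for (d in doms) {
    pm <- domain_enrichment_tests(pnets, d, exclude)
    for (l in labs) {
      others <- setdiff(labs, l)
      sig <- others[!is.na(pm[l, others]) & pm[l, others] <= alpha]
      if (length(sig) > 0L) {
        fl <- freq_of(profiles[[l]], d)
        fo <- mean(vapply(sig, function(o) freq_of(profiles[[o]], d),
                          numeric(1)))
        edges <- rbind(edges, data.frame(
          domain = d, isoform = l,
          sign = if (fl >= fo) "presence" else "absence",
          min_p = min(pm[l, sig]), stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(edges))
    edges <- data.frame(domain = character(0), isoform = character(0),
                        sign = character(0), min_p = numeric(0))
  degree <- table(factor(edges$domain, doms))
  structure(list(edges = edges, domains = doms, isoforms = labs,
                 domain_degree = stats::setNames(as.integer(degree), doms),
                 alpha = alpha),
            class = "domain_isoform_bipartite")
}

#' @export
print.domain_isoform_bipartite <- function(x, ...) {
  cat(sprintf("domain-isoform bipartite (alpha = %g): %d domains, %d edges\n",
              x$alpha, length(x$domains), nrow(x$edges)))
  invisible(x)
}

#' Frequencies of modified (phospho- or acetyl-) domains
#'
#' A domain instance counts as modified when at least one matching PTM site
#' falls within its coordinates; counting is protein-level as in
#' [domain_frequencies()].
#'
#' @param pnet A `paralog_network`.
#' @param modification `"phospho"` (any of pS/pT/pY) or `"acetyl"` (acK).
#' @param top_n Retain the top-n domains by frequency (default 5; `Inf` for
#'   all).
#' @param exclude Domains to omit (default `"CC"`).
#' @return data.frame like [domain_frequencies()].
#' @export
modified_domain_frequencies <- function(pnet,
                                        modification = c("phospho", "acetyl"),
                                        top_n = 5, exclude = "CC") {
  modification <- match.arg(modification)
  net <- pnet$net
  dom <- net$domains[net$domains$protein_id %in% pnet$partner_ids &
                       !net$domains$domain_name %in% exclude, , drop = FALSE]
  s <- partner_sites(pnet)
  s <- if (modification == "phospho")
    s[s$class %in% c("pS", "pT", "pY"), , drop = FALSE]
  else s[s$class == "acK", , drop = FALSE]
  n_part <- length(pnet$partner_ids)
  if (nrow(dom) == 0L || nrow(s) == 0L) {
    out <- data.frame(isoform = character(0), domain_name = character(0),
                      n_proteins = integer(0), frequency = numeric(0))
    attr(out, "n_partners") <- n_part
    return(out)
  }
  m <- merge(dom, s[, c("protein_id", "position")], by = "protein_id")
  hit <- m[m$position >= m$start & m$position <= m$end, , drop = FALSE]
  if (nrow(hit) == 0L) {
    out <- data.frame(isoform = character(0), domain_name = character(0),
                      n_proteins = integer(0), frequency = numeric(0))
    attr(out, "n_partners") <- n_part
    return(out)
  }
  prot <- table(unique(hit[, c("protein_id", "domain_name")])$domain_name)
  out <- data.frame(isoform = pnet$isoform, domain_name = names(prot),
                    n_proteins = as.integer(prot),
                    frequency = as.integer(prot) / n_part,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, -out$n_proteins, out$domain_name), ,
             drop = FALSE]
  if (is.finite(top_n)) out <- utils::head(out, top_n)
  rownames(out) <- NULL
  attr(out, "n_partners") <- n_part
  out
}

#' Clade ("domain club") profile of one paralog network
#'
#' Partners are assigned to clades 1-1250 via an externally supplied mapping
#' (the hierarchical domain-club clustering is consumed, not computed).
#' Clades up to `isolated_from - 1` contain social domains; clades from
#' `isolated_from` (default 1081) up are isolated domains branching directly
#' from the root.
#'
#' @param pnet A `paralog_network`.
#' @param clade_map data.frame (`protein_id`, `clade_id`); default: the
#'   network's clade table.
#' @param isolated_from First clade id of the isolated-domain range
#'   (default 1081; the published boundary is approximate).
#' @return List with `profile` (clade_id, count, frequency over mapped
#'   partners), `n_unmapped`, `isolated_fraction`.
#' @export
clade_profile <- function(pnet, clade_map = NULL, isolated_from = 1081) {
  if (is.null(clade_map)) clade_map <- pnet$net$clades
  bad <- clade_map$clade_id < 1 | clade_map$clade_id > 1250
  if (any(bad)) {
    warning(sum(bad), " clade row(s) outside 1-1250 rejected")
    clade_map <- clade_map[!bad, , drop = FALSE]
  }
  cl <- clade_map$clade_id[match(pnet$partner_ids, clade_map$protein_id)]
  mapped <- !is.na(cl)
  profile <- if (any(mapped)) {
    tab <- table(cl[mapped])
    data.frame(clade_id = as.integer(names(tab)), count = as.integer(tab),
               frequency = as.integer(tab) / sum(mapped))
  } else data.frame(clade_id = integer(0), count = integer(0),
                    frequency = numeric(0))
  list(profile = profile, n_unmapped = sum(!mapped),
       isolated_fraction = if (any(mapped))
         mean(cl[mapped] >= isolated_from) else NA_real_)
}
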