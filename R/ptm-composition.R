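# Region-stratified PTM composition per isoform network, cross-isoform
# contingency tests, acetylation burden, phospho/acetyl crosstalk and
# localization statistics.

#' Structural region of residue positions
#'
#' Maps positions of one protein to \{domain, disordered, other\}. When a
#' domain and a disorder segment overlap, the domain label takes precedence
#' (domains are the more specific curated annotation); configurable.
#'
#' @param net An `annotated_network`.
#' @param protein_id Single accession.
#' @param position Integer vector of 1-based positions within the protein.
#' @param precedence `"domain"` (default) or `"disordered"`: which label wins
#'   on overlap.
#' @return Character vector of region labels.
#' @export
classify_position <- function(net, protein_id, position,
                              precedence = c("domain", "disordered")) {
  precedence <- match.arg(precedence)
  len <- net$proteins$length[match(protein_id, net$proteins$protein_id)]
  if (is.na(len)) stop("unknown protein: ", protein_id)
  if (any(position < 1L | position > len))
    stop("position out of range 1..", len)
  sites <- data.frame(protein_id = protein_id, position = position)
  site_regions(net, sites, precedence)
}

# vectorized region labels for a site table (protein_id, position)
site_regions <- function(net, sites, precedence = "domain") {
  n <- nrow(sites)
  if (n == 0L) return(character(0))
  in_tab <- function(tab) {
    hit <- rep(FALSE, n)
    if (nrow(tab) == 0L) return(hit)
    m <- merge(cbind(sites[, c("protein_id", "position")], .row = seq_len(n)),
               tab, by = "protein_id")
    if (nrow(m) > 0L) {
      inside <- m$position >= m$start & m$position <= m$end
      hit[unique(m$.row[inside])] <- TRUE
    }
    hit
  }
  in_dom <- in_tab(net$domains)
  in_dis <- in_tab(net$disorder)
  out <- rep("other", n)
  if (precedence == "domain") {
    out[in_dis] <- "disordered"
    out[in_dom] <- "domain"
  } else {
    out[in_dom] <- "domain"
    out[in_dis] <- "disordered"
  }
  out
}

REGIONS <- c("domain", "disordered", "other")
PTM_CLASSES <- c("pS", "pT", "pY", "acK")

partner_sites <- function(pnet) {
  net <- pnet$net
  s <- net$ptms[net$ptms$protein_id %in% pnet$partner_ids, , drop = FALSE]
  s$class <- ptm_class(s)
  s <- s[!is.na(s$class), , drop = FALSE]
  s$region <- site_regions(net, s)
  s
}

#' Region-stratified PTM composition of one paralog network
#'
#' Counts modified residues of the partner proteins by PTM class (pS, pT,
#' pY, acK) and structural region; each site contributes to exactly one
#' (class, region) cell. A "total" region row sums the three regions.
#' Per-region percentages are computed for the phospho classes over all
#' phospho sites in that region; regions without phospho sites are flagged.
#'
#' @param pnet A `paralog_network`.
#' @return data.frame (`isoform`, `region`, `class`, `count`, `percent`) of
#'   class `composition_table`; attribute `no_phospho_regions`.
#' @export
composition_table <- function(pnet) {
  s <- partner_sites(pnet)
  tab <- table(factor(s$region, REGIONS), factor(s$class, PTM_CLASSES))
  tab <- rbind(tab, total = colSums(tab))
  out <- data.frame(isoform = pnet$isoform,
                    region = rep(rownames(tab), times = ncol(tab)),
                    class = rep(colnames(tab), each = nrow(tab)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  phos_tot <- rowSums(tab[, c("pS", "pT", "pY"), drop = FALSE])
  out$percent <- NA_real_
  is_ph <- out$class %in% c("pS", "pT", "pY")
  denom <- phos_tot[out$region]
  out$percent[is_ph] <- ifelse(denom[is_ph] > 0,
                               100 * out$count[is_ph] / denom[is_ph],
                               NA_real_)
  attr(out, "no_phospho_regions") <- names(phos_tot)[phos_tot == 0]
  class(out) <- c("composition_table", class(out))
  out
}

#' Per-partner PTM, disorder and localization profile
#'
#' One row per partner protein: site counts per PTM class, fraction of
#' residues in disordered segments, nuclear-localization and NLS flags.
#'
#' @param pnet A `paralog_network` (or a list with elements `net` and
#'   `partner_ids`).
#' @return data.frame keyed by `protein_id`.
#' @export
partner_profile <- function(pnet) {
  net <- pnet$net
  ids <- pnet$partner_ids
  prof <- data.frame(protein_id = ids, stringsAsFactors = FALSE)
  cm <- ptm_count_matrix(net)
  for (cls in PTM_CLASSES)
    prof[[paste0("n_", cls)]] <- as.integer(cm[ids, cls])
  len <- net$proteins$length[match(ids, net$proteins$protein_id)]
  dis <- net$disorder[net$disorder$protein_id %in% ids, , drop = FALSE]
  dis_res <- stats::setNames(rep(0, length(ids)), ids)
  if (nrow(dis) > 0L) {
    agg <- tapply(dis$end - dis$start + 1L, dis$protein_id, sum)
    dis_res[names(agg)] <- agg
  }
  prof$disorder_frac <- unname(dis_res[ids]) / len
  loc <- net$localization
  prof$nuclear <- ids %in% loc$protein_id[loc$label == "nuclear"]
  prof$has_nls <- net$proteins$has_nls[match(ids, net$proteins$protein_id)]
  prof
}

#' Pool the partners of several paralog networks into one pseudo-network
#'
#' Used for planted-effect detection: the network of one isoform is
#' contrasted against the union of the partners of the remaining isoforms.
#'
#' @param pnets Named list of `paralog_network`s.
#' @param exclude Isoform label(s) to leave out of the pool.
#' @return A `paralog_network`-shaped object with the pooled partner set.
#' @export
pooled_partners <- function(pnets, exclude = character(0)) {
  keep <- pnets[setdiff(names(pnets), exclude)]
  ids <- sort(unique(unlist(lapply(keep, function(p) p$partner_ids))))
  ids <- setdiff(ids, unlist(lapply(pnets, function(p) p$hub_id)))
  structure(list(isoform = paste0("pooled-", paste(exclude, collapse = "+")),
                 hub_id = NA_character_, partner_ids = ids,
                 node_ids = ids, edges = keep[[1]]$net$edges[0, ],
                 net = keep[[1]]$net),
            class = "paralog_network")
}

#' Compare a fraction between two networks by Fisher's exact test
#'
#' `counter` reduces a network to `c(successes, trials)`; the two networks'
#' counts form a 2x2 table (network x success/failure) tested two-sidedly.
#'
#' @param netA,netB `paralog_network`s (or pooled sets).
#' @param counter Function of one network returning `c(k, n)`; see
#'   [counter_pY_in_domain()], [counter_acetylated_partners()].
#' @return List with `table`, `p`, `fractions`.
#' @export
compare_fraction <- function(netA, netB, counter) {
  ka <- counter(netA); kb <- counter(netB)
  if (ka[2] == 0 || kb[2] == 0) stop("zero denominator in fraction comparison")
  tab <- matrix(c(ka[1], ka[2] - ka[1], kb[1], kb[2] - kb[1]),
                nrow = 2, byrow = TRUE,
                dimnames = list(c(netA$isoform, netB$isoform),
                                c("yes", "no")))
  list(table = tab, p = fisher_exact(tab)$p,
       fractions = c(ka[1] / ka[2], kb[1] / kb[2]))
}

#' @describeIn compare_fraction Counter: phospho-tyrosine sites among all
#'   phospho sites falling inside domains.
#' @param pnet A `paralog_network`.
#' @export
counter_pY_in_domain <- function(pnet) {
  s <- partner_sites(pnet)
  dom_ph <- s$region == "domain" & s$class %in% c("pS", "pT", "pY")
  c(sum(dom_ph & s$class == "pY"), sum(dom_ph))
}

#' @describeIn compare_fraction Counter: partners carrying at least one
#'   acetyl-lysine, among all partners.
#' @export
counter_acetylated_partners <- function(pnet) {
  prof <- partner_profile(pnet)
  c(sum(prof$n_acK > 0), nrow(prof))
}

#' Acetylation burden of each paralog network
#'
#' Per isoform: acetylated partners, acetyl-lysine site count, and acK sites
#' inside domains; plus the matrix of pairwise two-sided Fisher p-values on
#' the acetylated-partner proportions (raw p; a Benjamini-Hochberg column is
#' attached as `q_matrix`).
#'
#' @param pnets Named list of at least two `paralog_network`s.
#' @return List with `counts` (data.frame) and `p_matrix` (symmetric);
#'   attribute `q_matrix`.
#' @export
acetylation_burden <- function(pnets) {
  if (length(pnets) < 2L) stop("need at least two paralog networks")
  labs <- names(pnets)
  counts <- do.call(rbind, lapply(labs, function(l) {
    prof <- partner_profile(pnets[[l]])
    s <- partner_sites(pnets[[l]])
    data.frame(isoform = l, partners = nrow(prof),
               acetylated_partners = sum(prof$n_acK > 0),
               acK_sites = sum(prof$n_acK),
               acK_in_domain = sum(s$class == "acK" & s$region == "domain"),
               stringsAsFactors = FALSE)
  }))
  k <- length(labs)
  p <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    tab <- matrix(c(counts$acetylated_partners[i],
                    counts$partners[i] - counts$acetylated_partners[i],
                    counts$acetylated_partners[j],
                    counts$partners[j] - counts$acetylated_partners[j]),
                  2, byrow = TRUE)
    p[i, j] <- p[j, i] <- fisher_exact(tab)$p
  }
  q <- p
  up <- upper.tri(p)
  q[up] <- benjamini_hochberg(p[up])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  out <- list(counts = counts, p_matrix = p)
  attr(out, "q_matrix") <- q
  out
}

#' Phospho/acetyl crosstalk within one paralog network
#'
#' Protein-level 2x2 association between carrying at least one phospho site
#' of the given residue and carrying at least one acetyl-lysine, with a
#' two-sided Fisher p. A table with an empty margin (e.g. no acetylation at
#' all) is flagged degenerate with p = 1.
#'
#' @param pnet A `paralog_network`.
#' @param phospho_residue `"S"`, `"T"` or `"Y"`.
#' @return List with `table`, `p`, `degenerate`.
#' @export
crosstalk_association <- function(pnet, phospho_residue = c("Y", "S", "T")) {
  phospho_residue <- match.arg(phospho_residue)
  prof <- partner_profile(pnet)
  has_ph <- prof[[paste0("n_p", phospho_residue)]] > 0
  has_ac <- prof$n_acK > 0
  tab <- matrix(c(sum(has_ph & has_ac), sum(has_ph & !has_ac),
                  sum(!has_ph & has_ac), sum(!has_ph & !has_ac)),
                2, byrow = TRUE,
                dimnames = list(c("phospho", "no_phospho"),
                                c("acK", "no_acK")))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (degenerate) 1 else fisher_exact(tab)$p
  list(table = tab, p = p, degenerate = degenerate)
}

#' Ordinary least-squares proportionality fit
#'
#' @param x,y Numeric vectors (>= 3 points) of per-isoform totals.
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
proportionality_fit <- function(x, y) {
  if (length(x) < 3L || length(y) != length(x))
    stop("need >= 3 paired points")
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::var(y) == 0) 0 else
    suppressWarnings(summary(fit)$r.squared)  # exact fits warn harmlessly
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}

#' Kinase-group involvement profile across paralog networks
#'
#' For every network, the relative frequency of each kinase group among the
#' kinases present in the network's node set; rows normalized to 1. Kinases
#' without a group mapping count as "other" (logged); networks without
#' kinases yield a zero row, flagged.
#'
#' @param pnets Named list of `paralog_network`s.
#' @param kinase_group_map Optional data.frame (`protein_id`, `group`);
#'   default: the networks' own kinase-group table.
#' @return Matrix isoform x group; attributes `zero_rows`, `n_unmapped`.
#' @export
kinase_group_profile <- function(pnets, kinase_group_map = NULL) {
  labs <- names(pnets)
  groups <- KINASE_GROUPS
  m <- matrix(0, length(labs), length(groups),
              dimnames = list(labs, groups))
  unmapped <- 0L
  for (l in labs) {
    net <- pnets[[l]]$net
    kin <- intersect(pnets[[l]]$node_ids,
                     net$proteins$protein_id[net$proteins$is_kinase])
    map <- if (is.null(kinase_group_map)) net$kinase_groups else kinase_group_map
    g <- map$group[match(kin, map$protein_id)]
    unmapped <- unmapped + sum(is.na(g))
    g[is.na(g) | !g %in% groups] <- "other"
    if (length(g) > 0L) {
      tab <- table(factor(g, groups))
      m[l, ] <- as.numeric(tab) / sum(tab)
    }
  }
  zero <- labs[rowSums(m) == 0]
  attr(m, "zero_rows") <- zero
  attr(m, "n_unmapped") <- unmapped
  m
}

#' Localization statistics of a partner subset
#'
#' For the subset of partners selected by `subset` (a predicate over the
#' [partner_profile()] rows, or a vector of accessions): subset share of all
#' partners, nuclear share within the subset, share of all NLS-bearing
#' partners captured by the subset, and the Fisher test of NLS concentration
#' (in-subset x has-NLS over all partners).
#'
#' @param pnet A `paralog_network`.
#' @param subset Function(profile) -> logical, or character vector of ids.
#' @return List with `fractions`, `table`, `p`, `degenerate`.
#' @export
localization_stats <- function(pnet, subset) {
  prof <- partner_profile(pnet)
  if (nrow(prof) == 0L || !any(prof$nuclear | !prof$nuclear))
    stop("no partners")
  if (nrow(pnet$net$localization) == 0L)
    stop("no localization data loaded; supply localization.tsv")
  sel <- if (is.function(subset)) subset(prof) else
    prof$protein_id %in% subset
  n_sub <- sum(sel)
  degenerate <- n_sub == 0L || n_sub == nrow(prof)
  fractions <- c(
    subset_share = n_sub / nrow(prof),
    nuclear_in_subset = if (n_sub > 0) mean(prof$nuclear[sel]) else NA_real_,
    nls_share = if (sum(prof$has_nls) > 0)
      sum(prof$has_nls & sel) / sum(prof$has_nls) else NA_real_)
  tab <- matrix(c(sum(sel & prof$has_nls), sum(sel & !prof$has_nls),
                  sum(!sel & prof$has_nls), sum(!sel & !prof$has_nls)),
                2, byrow = TRUE,
                dimnames = list(c("in_subset", "out"), c("NLS", "no_NLS")))
  p <- if (degenerate) 1 else fisher_exact(tab)$p
  list(fractions = fractions, table = tab, p = p, degenerate = degenerate)
}

#' Cross-isoform comparison of partner disorder content
#'
#' Disorder fraction per partner, compared across the seven networks three
#' ways: Kruskal-Wallis over all, pairwise Wilcoxon rank-sum, and pairwise
#' Fisher tests on partners binarized at a disorder-fraction threshold.
#'
#' @param pnets Named list of `paralog_network`s.
#' @param threshold Disorder-fraction cut for the binarized Fisher tests
#'   (default 0.5).
#' @return List with `kruskal` (list), `wilcoxon_p`, `fisher_p` (symmetric
#'   matrices), `threshold`.
#' @export
compare_disorder_content <- function(pnets, threshold = 0.5) {
  labs <- names(pnets)
  fracs <- lapply(pnets, function(p) partner_profile(p)$disorder_frac)
  kw <- kruskal_wallis(fracs)
  k <- length(labs)
  wp <- fp <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    wp[i, j] <- wp[j, i] <- wilcoxon_rank_sum(fracs[[i]], fracs[[j]])$p
    hi <- c(sum(fracs[[i]] >= threshold), sum(fracs[[j]] >= threshold))
    n <- c(length(fracs[[i]]), length(fracs[[j]]))
    fp[i, j] <- fp[j, i] <- fisher_exact(matrix(c(hi[1], n[1] - hi[1],
                                                  hi[2], n[2] - hi[2]),
                                                2, byrow = TRUE))$p
  }
  list(kruskal = kw, wilcoxon_p = wp, fisher_p = fp, threshold = threshold)
}
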