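# Ground-truth-labelled synthetic input bundles emulating the statistical
# structure the comparative analysis assumes: seven hub-centred partner sets
# with controlled overlap, domain architectures with disorder outside
# domains, phosphosites enriched in disordered regions and acetyl-lysines in
# ordered ones, isoform-specific effect multipliers, directed
# kinase->substrate edges, planted feed-forward loops, and a toy GO DAG.

#' Synthetic-cohort generator configuration
#'
#' Defaults define the reference study conditions; [null_config()] switches
#' every planted effect off for type-I calibration.
#'
#' @param seed Integer seed; the whole bundle is a deterministic function of
#'   the configuration including the seed.
#' @param n_proteins Total proteins (clients + kinases), default 800.
#' @param n_partners Partner-set size per isoform hub, default 120.
#' @param jaccard_base Target partner-set Jaccard for unrelated isoform
#'   pairs (default 0.10, realized through a core shared by all seven).
#' @param jaccard_pairs Named list pair-label -> target Jaccard for
#'   designated pairs; default theta-beta at 0.273.
#' @param kinase_frac Fraction of proteins that are kinases (default 0.15).
#' @param length_meanlog,length_sdlog Log-normal protein length (median 450).
#' @param domain_count_mean Mean per-protein domain count (geometric, 1.6).
#' @param domain_len Domain length range (uniform, 60-250).
#' @param disorder_shape1,disorder_shape2 Beta parameters of the per-protein
#'   disorder fraction (mean 1/3).
#' @param disorder_overlap_p Probability that a disorder segment may extend
#'   into a domain (default 0.1).
#' @param ptm_rates Site density per residue, region x class matrix.
#' @param mult_epsilon_pY_domain,mult_zeta_acK,mult_gamma_RRM,mult_go_boost
#'   Planted effect multipliers (2.5, 2.0, 8, 5).
#' @param planted_ffl Number of feed-forward loops planted in the directed
#'   layer (default 40).
#' @param kinase_out_mean Mean substrates per kinase (Poisson, 3).
#' @param background_edges Undirected client-client background interactions
#'   (default 150).
#' @param kinase_group_weights Sampling weights of the kinase groups.
#' @param domain_weights Sampling weights of the domain vocabulary.
#' @param dir_b_kinase,dir_b_degree,dir_b_ptm Logistic coefficients of the
#'   edge-direction model over the default feature schema.
#' @param go_terms,go_rate_range Toy ontology size (60 terms, 3 levels) and
#'   per-leaf-term annotation rate range.
#' @param p_nuclear_base,p_nuclear_acet,p_nls_nuclear,p_nls_other
#'   Localization model: nuclear probability for non-acetylated vs
#'   acetylated proteins, NLS probability given localization.
#' @param glyco_rate Background density of a non-phospho/acetyl
#'   modification class (exercises the "other PTM types" path).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_proteins = 800L,
                       n_partners = 120L,
                       jaccard_base = 0.10,
                       jaccard_pairs = list("theta|beta" = 0.273),
                       kinase_frac = 0.15,
                       length_meanlog = log(450), length_sdlog = 0.45,
                       domain_count_mean = 1.6,
                       domain_len = c(60L, 250L),
                       disorder_shape1 = 1.5, disorder_shape2 = 3,
                       disorder_overlap_p = 0.1,
                       ptm_rates = default_ptm_rates(),
                       mult_epsilon_pY_domain = 2.5,
                       mult_zeta_acK = 2.0,
                       mult_gamma_RRM = 8,
                       mult_go_boost = 5,
                       planted_ffl = 40L,
                       kinase_out_mean = 3,
                       background_edges = 150L,
                       kinase_group_weights = default_kinase_group_weights(),
                       domain_weights = default_domain_weights(),
                       dir_b_kinase = 2.2, dir_b_degree = 1.4,
                       dir_b_ptm = 0.5,
                       go_terms = 60L, go_rate_range = c(0.02, 0.08),
                       p_nuclear_base = 0.25, p_nuclear_acet = 0.65,
                       p_nls_nuclear = 0.55, p_nls_other = 0.08,
                       glyco_rate = 3e-4) {
  cfg <- as.list(environment())
  stopifnot(all(unlist(cfg[grep("^mult_", names(cfg))]) > 0),
            jaccard_base >= 0, jaccard_base <= 1, kinase_frac > 0,
            kinase_frac < 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Default PTM site densities per residue, by structural region
#'
#' Phosphoserine/-threonine concentrate in disordered segments,
#' phosphotyrosine is relatively domain-enriched, and acetyl-lysine favours
#' ordered (domain) regions.
#'
#' @return Matrix region x class (pS, pT, pY, acK).
#' @export
default_ptm_rates <- function() {
  # site density per residue position, by structural region
  m <- rbind(domain     = c(pS = 0.004, pT = 0.002, pY = 0.003, acK = 0.006),
             disordered = c(pS = 0.020, pT = 0.010, pY = 0.002, acK = 0.002),
             other      = c(pS = 0.008, pT = 0.004, pY = 0.002, acK = 0.003))
  m
}

default_kinase_group_weights <- function()
  c(AGC = 0.18, CAMK = 0.12, CK1 = 0.04, CMGC = 0.20, STE = 0.10,
    TK = 0.14, TKL = 0.08, atypical = 0.08, other = 0.06)

default_domain_weights <- function()
  c(S_T_Kinase = 0.10, Tyr_Kinase = 0.05, SH3 = 0.06, SH2 = 0.05,
    PDZ = 0.05, WD40 = 0.06, RRM = 0.06, TPR = 0.05, HAT = 0.03,
    LIM = 0.04, KELCH = 0.03, EF = 0.05, LRR = 0.04, PH = 0.05,
    ANK = 0.05, ZnF = 0.05, CC = 0.08, TM = 0.07, PEST = 0.03)

#' Neutralize every planted effect of a configuration
#'
#' Sets all isoform-specific multipliers to 1, removes planted motifs and
#' equalizes the acetylation-localization coupling; used for type-I error
#' calibration of the whole pipeline.
#'
#' @param config A `sim_config`.
#' @return The null configuration.
#' @export
null_config <- function(config) {
  config$mult_epsilon_pY_domain <- 1
  config$mult_zeta_acK <- 1
  config$mult_gamma_RRM <- 1
  config$mult_go_boost <- 1
  config$planted_ffl <- 0L
  config$p_nuclear_acet <- config$p_nuclear_base
  config
}

# partner-set construction: a core shared by all seven isoforms realizes the
# base Jaccard; designated pairs get an extra shared block on top.
partner_set_plan <- function(config) {
  s <- config$n_partners
  core <- round(2 * s * config$jaccard_base / (1 + config$jaccard_base))
  pairs <- lapply(names(config$jaccard_pairs), function(key) {
    iso <- strsplit(key, "|", fixed = TRUE)[[1]]
    j <- config$jaccard_pairs[[key]]
    extra <- round(2 * s * j / (1 + j)) - core
    if (extra < 0)
      stop("pair target Jaccard below the base target for ", key)
    list(iso = iso, extra = extra)
  })
  labs <- names(ISOFORM_ACCESSIONS)
  extra_of <- stats::setNames(rep(0L, 7), labs)
  for (p in pairs) extra_of[p$iso] <- extra_of[p$iso] + p$extra
  private <- s - core - extra_of
  if (any(private < 0))
    stop("infeasible overlap targets: shared blocks exceed the set size ",
         s, "; feasible base Jaccard < ", round(s / (2 * s - s), 3))
  demand <- core + sum(vapply(pairs, function(p) p$extra, numeric(1))) +
    sum(private)
  list(core = core, pairs = pairs, private = private, demand = demand)
}

#' Generate a synthetic cohort in memory
#'
#' Produces all input tables plus the ground truth. Deterministic: the same
#' configuration (including seed) yields identical tables.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_bundle` with elements `proteins`, `lengths`,
#'   `interactions`, `ptm`, `domains`, `disorder`, `go`, `dag`,
#'   `localization`, `kinase_groups`, `clades`, `train`, `directions`
#'   (truth for every edge), and `truth`.
#' @export
simulate_cohort <- function(config) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  n <- config$n_proteins
  n_kin <- round(config$kinase_frac * n)
  ids <- sprintf("SYN%05d", seq_len(n))
  kinase_ids <- sort(sample(ids, n_kin))
  client_ids <- setdiff(ids, kinase_ids)

  plan <- partner_set_plan(config)
  if (plan$demand > length(client_ids))
    stop("infeasible configuration: partner construction needs ",
         plan$demand, " distinct clients but only ", length(client_ids),
         " exist; increase n_proteins or reduce n_partners")
  pool <- sample(client_ids)
  take <- function(k) {
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  labs <- names(ISOFORM_ACCESSIONS)
  core <- take(plan$core)
  partner_sets <- stats::setNames(lapply(labs, function(l) core), labs)
  for (p in plan$pairs) {
    blk <- take(p$extra)
    for (l in p$iso) partner_sets[[l]] <- c(partner_sets[[l]], blk)
  }
  for (l in labs)
    partner_sets[[l]] <- sort(c(partner_sets[[l]], take(plan$private[[l]])))

  lengths <- pmax(80L, pmin(3000L, round(stats::rlnorm(
    n, config$length_meanlog, config$length_sdlog))))
  names(lengths) <- ids

  kin_groups <- sample(names(config$kinase_group_weights), n_kin,
                       replace = TRUE, prob = config$kinase_group_weights)
  names(kin_groups) <- kinase_ids

  gamma_partners <- partner_sets$gamma
  epsilon_partners <- partner_sets$epsilon
  zeta_partners <- partner_sets$zeta

  # --- domains -------------------------------------------------------------
  dw <- config$domain_weights
  dom_rows <- vector("list", n)
  geo_p <- 1 / (1 + config$domain_count_mean)
  counts <- stats::rgeom(n, geo_p)
  for (i in seq_len(n)) {
    id <- ids[i]; L <- lengths[i]
    w <- dw
    if (id %in% gamma_partners) w["RRM"] <- w["RRM"] * config$mult_gamma_RRM
    k <- counts[i]
    nm <- if (k > 0) sample(names(w), k, replace = TRUE, prob = w) else
      character(0)
    if (id %in% kinase_ids) {
      kd <- if (kin_groups[id] == "TK") "Tyr_Kinase" else "S_T_Kinase"
      nm <- c(kd, nm)
    }
    if (length(nm) == 0L) { dom_rows[[i]] <- NULL; next }
    # non-overlapping placement: keep domains while the architecture fits
    # within 85% of the chain, then distribute the slack as random gaps
    lens <- pmin(sample(config$domain_len[1]:config$domain_len[2],
                        length(nm), replace = TRUE), floor(0.8 * L))
    keep <- cumsum(lens) <= 0.85 * L
    nm <- nm[keep]; lens <- lens[keep]
    k <- length(nm)
    if (k == 0L) { dom_rows[[i]] <- NULL; next }
    slack <- L - sum(lens)
    offs <- sort(sample.int(slack + 1L, k, replace = TRUE)) - 1L
    st <- offs + c(0L, cumsum(lens)[-k]) + 1L
    en <- st + lens - 1L
    dom_rows[[i]] <- data.frame(protein_id = id, domain_name = nm,
                                start = st, end = en,
                                stringsAsFactors = FALSE)
  }
  domains <- do.call(rbind, dom_rows)
  if (is.null(domains)) domains <- empty_domains()

  # --- disorder (placed in the gaps between domains) -----------------------
  dis_rows <- vector("list", n)
  fracs <- stats::rbeta(n, config$disorder_shape1, config$disorder_shape2)
  dom_by_prot <- split(domains[, c("start", "end")], domains$protein_id)
  for (i in seq_len(n)) {
    id <- ids[i]; L <- lengths[i]
    target <- round(fracs[i] * L)
    if (target < 10L) next
    dd <- dom_by_prot[[id]]
    gaps <- if (is.null(dd)) data.frame(start = 1L, end = L) else {
      dd <- dd[order(dd$start), , drop = FALSE]
      gs <- c(1L, dd$end + 1L)
      ge <- c(dd$start - 1L, L)
      ok <- gs <= ge
      data.frame(start = gs[ok], end = ge[ok])
    }
    if (nrow(gaps) == 0L) next
    gaps <- gaps[sample.int(nrow(gaps)), , drop = FALSE]
    st <- en <- integer(0)
    left <- target
    for (g in seq_len(nrow(gaps))) {
      if (left <= 0L) break
      glen <- gaps$end[g] - gaps$start[g] + 1L
      use <- min(glen, left)
      s0 <- gaps$start[g]
      e0 <- s0 + use - 1L
      if (stats::runif(1) < config$disorder_overlap_p)
        e0 <- min(L, e0 + sample.int(30L, 1))  # may run into a domain
      st <- c(st, s0); en <- c(en, e0)
      left <- left - (e0 - s0 + 1L)
    }
    if (length(st) > 0L)
      dis_rows[[i]] <- data.frame(protein_id = id, start = st, end = en,
                                  stringsAsFactors = FALSE)
  }
  disorder <- do.call(rbind, dis_rows)
  if (is.null(disorder)) disorder <- empty_segments()
  disorder <- merge_segments(disorder)

  # --- PTM sites: per-residue Bernoulli with region-dependent rates --------
  off <- c(0L, cumsum(lengths))
  total_res <- off[n + 1L]
  region <- rep.int(1L, total_res)               # 1 = other
  mark <- function(tab, code) {
    if (nrow(tab) == 0L) return()
    w <- tab$end - tab$start + 1L
    gidx <- sequence(nvec = w, from = off[match(tab$protein_id, ids)] +
                       tab$start)
    region[gidx] <<- code
  }
  mark(disorder, 2L)                              # 2 = disordered
  mark(domains, 3L)                               # 3 = domain (precedence)
  prot_of_res <- rep.int(seq_len(n), lengths)
  region_name <- c("other", "disordered", "domain")[region]

  rates <- config$ptm_rates
  in_set <- function(set) ids[prot_of_res] %in% set
  eps_res <- in_set(epsilon_partners)
  zeta_res <- in_set(zeta_partners)
  site_list <- list()
  for (cls in PTM_CLASSES) {
    r <- rates[region_name, cls]
    if (cls == "pY")
      r <- ifelse(eps_res & region_name == "domain",
                  r * config$mult_epsilon_pY_domain, r)
    if (cls == "acK")
      r <- ifelse(zeta_res, r * config$mult_zeta_acK, r)
    hit <- which(stats::runif(total_res) < r)
    if (length(hit) == 0L) next
    pid <- prot_of_res[hit]
    site_list[[cls]] <- data.frame(
      protein_id = ids[pid],
      position = as.integer(hit - off[pid]),
      residue = c(pS = "S", pT = "T", pY = "Y", acK = "K")[[cls]],
      modification = if (cls == "acK") "acetylation" else "phosphorylation",
      region = region_name[hit], stringsAsFactors = FALSE)
  }
  gly <- which(stats::runif(total_res) < config$glyco_rate)
  if (length(gly) > 0L) {
    pid <- prot_of_res[gly]
    site_list$gly <- data.frame(protein_id = ids[pid],
                                position = as.integer(gly - off[pid]),
                                residue = "N",
                                modification = "glycosylation",
                                region = region_name[gly],
                                stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, site_list)
  if (is.null(sites))
    sites <- data.frame(protein_id = character(0), position = integer(0),
                        residue = character(0), modification = character(0),
                        region = character(0))
  sites <- sites[!duplicated(paste(sites$protein_id, sites$position)), ,
                 drop = FALSE]
  sites <- sites[order(sites$protein_id, sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  ptm <- sites[, c("protein_id", "position", "residue", "modification")]

  # --- localization + NLS (acetylation-coupled) ----------------------------
  has_ack <- ids %in% sites$protein_id[sites$modification == "acetylation"]
  p_nuc <- ifelse(has_ack, config$p_nuclear_acet, config$p_nuclear_base)
  nuclear <- stats::runif(n) < p_nuc
  loc_label <- ifelse(nuclear, "nuclear",
                      ifelse(stats::runif(n) < 0.8, "cytoplasmic",
                             "membrane"))
  localization <- data.frame(protein_id = ids, label = loc_label,
                             stringsAsFactors = FALSE)
  dual <- nuclear & stats::runif(n) < 0.2
  if (any(dual))
    localization <- rbind(localization,
                          data.frame(protein_id = ids[dual],
                                     label = "cytoplasmic"))
  p_nls <- ifelse(nuclear, config$p_nls_nuclear, config$p_nls_other)
  nls <- stats::runif(n) < p_nls
  if (any(nls)) {
    pos <- vapply(lengths[nls], function(L) sample.int(L - 10L, 1),
                  integer(1))
    domains <- rbind(domains,
                     data.frame(protein_id = ids[nls], domain_name = "NLS",
                                start = pos, end = pos + 9L,
                                stringsAsFactors = FALSE))
  }
  domains <- domains[order(domains$protein_id, domains$start,
                           domains$domain_name), , drop = FALSE]
  rownames(domains) <- NULL
  # NLS motifs entered the domain table after site placement; restate the
  # truth region of any site they cover (domain precedence)
  nls_tab <- domains[domains$domain_name == "NLS", , drop = FALSE]
  if (nrow(nls_tab) > 0L && nrow(sites) > 0L) {
    m <- merge(cbind(sites[, c("protein_id", "position")],
                     .r = seq_len(nrow(sites))), nls_tab, by = "protein_id")
    hit <- unique(m$.r[m$position >= m$start & m$position <= m$end])
    sites$region[hit] <- "domain"
  }

  # --- edges ---------------------------------------------------------------
  hub_edges <- do.call(rbind, lapply(labs, function(l)
    data.frame(id_a = ISOFORM_ACCESSIONS[[l]], id_b = partner_sets[[l]],
               source = "sim:hub", stringsAsFactors = FALSE)))
  n_sub <- stats::rpois(n_kin, config$kinase_out_mean)
  kin_edges <- do.call(rbind, lapply(seq_len(n_kin), function(i) {
    if (n_sub[i] == 0L) return(NULL)
    subs <- sample(client_ids, min(n_sub[i], length(client_ids)))
    data.frame(id_a = kinase_ids[i], id_b = subs, source = "sim:kinase",
               stringsAsFactors = FALSE)
  }))
  train <- if (is.null(kin_edges))
    data.frame(from = character(0), to = character(0)) else
      data.frame(from = kin_edges$id_a, to = kin_edges$id_b,
                 stringsAsFactors = FALSE)
  bg_a <- sample(client_ids, config$background_edges, replace = TRUE)
  bg_b <- sample(client_ids, config$background_edges, replace = TRUE)
  keep <- bg_a != bg_b
  bg_edges <- data.frame(id_a = bg_a[keep], id_b = bg_b[keep],
                         source = "sim:background", stringsAsFactors = FALSE)
  ffl_edges <- NULL
  ffl_triples <- NULL
  if (config$planted_ffl > 0L) {
    tri <- matrix(sample(client_ids, 3L * config$planted_ffl), ncol = 3)
    ffl_triples <- data.frame(x = tri[, 1], y = tri[, 2], z = tri[, 3],
                              stringsAsFactors = FALSE)
    ffl_edges <- data.frame(
      id_a = c(tri[, 1], tri[, 1], tri[, 2]),
      id_b = c(tri[, 2], tri[, 3], tri[, 3]),
      source = "sim:ffl", stringsAsFactors = FALSE)
  }
  all_edges <- rbind(hub_edges, kin_edges, bg_edges, ffl_edges)
  # fixed-direction truth before undirected dedup: feed-forward loops first,
  # then curated kinase edges
  fixed_from <- c(ffl_edges$id_a, kin_edges$id_a)
  fixed_to <- c(ffl_edges$id_b, kin_edges$id_b)
  fkey <- paste(pmin(fixed_from, fixed_to), pmax(fixed_from, fixed_to),
                sep = "\r")
  first <- !duplicated(fkey)
  fixed <- data.frame(from = fixed_from[first], to = fixed_to[first],
                      key = fkey[first], stringsAsFactors = FALSE)
  interactions <- normalize_edges(all_edges)

  # degree/PTM-driven direction model for the remaining (hub + background)
  deg <- table(c(interactions$id_a, interactions$id_b))
  degv <- stats::setNames(rep(0L, n + 7L), c(ids, unname(ISOFORM_ACCESSIONS)))
  degv[names(deg)] <- as.integer(deg)
  nsite <- table(ptm$protein_id)
  nsitev <- stats::setNames(rep(0L, n + 7L),
                            c(ids, unname(ISOFORM_ACCESSIONS)))
  nsitev[names(nsite)] <- as.integer(nsite)
  brks <- ptm_breaks(as.numeric(nsitev))
  binv <- as.integer(factor(bin_counts(as.numeric(nsitev), brks),
                            levels = c("low", "mid", "high")))
  names(binv) <- names(nsitev)
  is_kin <- stats::setNames(c(ids %in% kinase_ids, rep(FALSE, 7L)),
                            c(ids, unname(ISOFORM_ACCESSIONS)))
  a <- interactions$id_a; b <- interactions$id_b
  logit <- config$dir_b_kinase * (is_kin[a] - is_kin[b]) +
    config$dir_b_degree * sign(degv[a] - degv[b]) +
    config$dir_b_ptm * (binv[a] - binv[b])
  fwd <- stats::runif(nrow(interactions)) < stats::plogis(logit)
  directions <- data.frame(
    from = ifelse(fwd, a, b), to = ifelse(fwd, b, a),
    stringsAsFactors = FALSE)
  ekey <- paste(interactions$id_a, interactions$id_b, sep = "\r")
  hit <- match(ekey, fixed$key)
  ov <- !is.na(hit)
  directions$from[ov] <- fixed$from[hit[ov]]
  directions$to[ov] <- fixed$to[hit[ov]]

  # --- toy GO DAG + annotations -------------------------------------------
  godat <- simulate_go(config, ids, gamma_partners)

  # --- clades --------------------------------------------------------------
  stk <- unique(domains$protein_id[domains$domain_name == "S_T_Kinase"])
  tpr <- unique(domains$protein_id[domains$domain_name %in% c("TPR", "HAT")])
  clade <- sample(1:1080, n, replace = TRUE,
                  prob = 1 / sqrt(1:1080))  # few big social clades
  names(clade) <- ids
  clade[intersect(ids, stk)] <- sample(c(172L, 566L),
                                       length(intersect(ids, stk)),
                                       replace = TRUE)
  clade[intersect(ids, tpr)] <- 224L
  iso_cand <- setdiff(zeta_partners, c(stk, tpr))
  iso_pick <- iso_cand[stats::runif(length(iso_cand)) < 0.15]
  clade[iso_pick] <- sample(1081:1250, length(iso_pick), replace = TRUE)
  clades <- data.frame(protein_id = ids, clade_id = as.integer(clade),
                       stringsAsFactors = FALSE)

  proteins <- data.frame(protein_id = c(ids, unname(ISOFORM_ACCESSIONS)),
                         length = c(as.integer(lengths),
                                    rep(245L, 7L)),  # 14-3-3 monomer length
                         stringsAsFactors = FALSE)
  kinase_groups <- data.frame(protein_id = kinase_ids,
                              group = unname(kin_groups),
                              stringsAsFactors = FALSE)
  truth <- list(
    partner_sets = partner_sets,
    multipliers = list(epsilon_pY_domain = config$mult_epsilon_pY_domain,
                       zeta_acK = config$mult_zeta_acK,
                       gamma_RRM = config$mult_gamma_RRM,
                       go_boost = config$mult_go_boost),
    boost_term = godat$boost_term,
    planted_ffls = ffl_triples,
    site_regions = sites[, c("protein_id", "position", "region")],
    kinase_ids = kinase_ids)
  structure(list(proteins = proteins, interactions = interactions,
                 ptm = ptm, domains = domains, disorder = disorder,
                 go = godat$annotations, dag = godat$dag,
                 localization = localization,
                 kinase_groups = kinase_groups, clades = clades,
                 train = train, directions = directions, truth = truth,
                 config = config),
            class = "sim_bundle")
}

simulate_go <- function(config, ids, gamma_partners) {
  n_terms <- config$go_terms
  n_l2 <- 12L
  term_ids <- sprintf("GO:S%04d", seq_len(n_terms))
  ns <- c("biological_process", "cellular_component")
  namespace <- character(n_terms)
  namespace[1:2] <- ns
  namespace[3:(2 + n_l2)] <- rep(ns, times = c(8L, 4L))
  n_l3 <- n_terms - 2L - n_l2
  namespace[(3 + n_l2):n_terms] <- sample(rep(ns, length.out = n_l3))
  level <- c(1L, 1L, rep(2L, n_l2), rep(3L, n_l3))
  parent_edges <- NULL
  for (i in which(level == 2L))
    parent_edges <- rbind(parent_edges,
                          data.frame(term_id = term_ids[i],
                                     parent_id = term_ids[match(namespace[i],
                                                                ns)]))
  for (i in which(level == 3L)) {
    cand <- term_ids[level == 2L & namespace == namespace[i]]
    k <- min(length(cand), sample(1:2, 1))
    parent_edges <- rbind(parent_edges,
                          data.frame(term_id = term_ids[i],
                                     parent_id = sample(cand, k)))
  }
  terms <- data.frame(term_id = term_ids,
                      name = paste0("toy process ", seq_len(n_terms)),
                      namespace = namespace, stringsAsFactors = FALSE)
  dag <- ontology_dag(terms, parent_edges)
  leaf_bp <- term_ids[level == 3L & namespace == "biological_process"]
  boost_term <- leaf_bp[1]
  ann <- NULL
  rates <- stats::runif(sum(level == 3L), config$go_rate_range[1],
                        config$go_rate_range[2])
  l3 <- which(level == 3L)
  for (j in seq_along(l3)) {
    r <- rep(rates[j], length(ids))
    if (term_ids[l3[j]] == boost_term)
      r[ids %in% gamma_partners] <- r[ids %in% gamma_partners] *
        config$mult_go_boost
    hit <- stats::runif(length(ids)) < pmin(r, 1)
    if (any(hit))
      ann <- rbind(ann, data.frame(protein_id = ids[hit],
                                   term_id = term_ids[l3[j]],
                                   stringsAsFactors = FALSE))
  }
  if (is.null(ann))
    ann <- data.frame(protein_id = character(0), term_id = character(0))
  list(dag = dag, annotations = ann, boost_term = boost_term,
       parent_edges = parent_edges)
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf("synthetic bundle (seed %d): %d proteins, %d interactions, %d PTM sites\n",
              x$config$seed, nrow(x$proteins), nrow(x$interactions),
              nrow(x$ptm)))
  invisible(x)
}

#' Assemble the annotated network of a synthetic bundle
#'
#' @param bundle A `sim_bundle`.
#' @return `annotated_network` built through the same assembly path as
#'   file-based inputs, with true protein lengths supplied.
#' @export
bundle_network <- function(bundle) {
  ann <- list(domains = bundle$domains, disorder = bundle$disorder,
              go = bundle$go, localization = bundle$localization,
              kinase_groups = bundle$kinase_groups, clades = bundle$clades)
  ptms <- validate_ptm_sites(bundle$ptm)
  assemble_full_network(bundle$interactions, ann, ptms,
                        lengths = bundle$proteins)
}

#' Ground-truth directed layer of a bundle
#'
#' The directed edges among kinases and clients (curated kinase->substrate
#' edges, the background interactions, and any planted feed-forward loops),
#' excluding the seven hub stars; this is the layer whose motif content the
#' census analyses and the randomization null is calibrated on.
#'
#' @param bundle A `sim_bundle`.
#' @return data.frame (`from`, `to`).
#' @export
directed_layer <- function(bundle) {
  hubs <- unname(ISOFORM_ACCESSIONS)
  d <- bundle$directions
  d[!(d$from %in% hubs | d$to %in% hubs), , drop = FALSE]
}

#' Write a synthetic bundle to disk
#'
#' Emits every input format of the pipeline (interactions.tsv, ptm.tsv,
#' domains.tsv, disorder.tsv, go.tsv, go.obo, localization.tsv,
#' kinase_groups.tsv, clades.tsv, train.tsv) plus truth.json; the same
#' configuration writes byte-identical files.
#'
#' @param config A [sim_config()] (or an existing `sim_bundle`).
#' @param out_dir Output directory (created if needed).
#' @return The `sim_bundle`, invisibly, with attribute `paths`.
#' @export
generate_bundle <- function(config, out_dir) {
  bundle <- if (inherits(config, "sim_bundle")) config else
    simulate_cohort(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    interactions = wt(bundle$interactions, "interactions.tsv"),
    ptm = wt(bundle$ptm, "ptm.tsv"),
    domains = wt(bundle$domains, "domains.tsv"),
    disorder = wt(bundle$disorder, "disorder.tsv"),
    go = wt(bundle$go, "go.tsv"),
    localization = wt(bundle$localization, "localization.tsv"),
    kinase_groups = wt(bundle$kinase_groups, "kinase_groups.tsv"),
    clades = wt(bundle$clades, "clades.tsv"),
    train = wt(bundle$train, "train.tsv"),
    lengths = wt(bundle$proteins, "lengths.tsv"))
  obo <- file.path(out_dir, "go.obo")
  write_obo(bundle$dag, obo)
  paths["obo"] <- obo
  tj <- file.path(out_dir, "truth.json")
  jsonlite::write_json(list(
    partner_sets = bundle$truth$partner_sets,
    multipliers = bundle$truth$multipliers,
    boost_term = bundle$truth$boost_term,
    planted_ffls = bundle$truth$planted_ffls,
    seed = bundle$config$seed), tj, auto_unbox = TRUE, digits = NA)
  paths["truth"] <- tj
  attr(bundle, "paths") <- paths
  invisible(bundle)
}

write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$term_id[i]
    writeLines(c("[Term]",
                 paste0("id: ", id),
                 paste0("name: ", dag$terms$name[i]),
                 paste0("namespace: ", dag$terms$namespace[i]),
                 paste0("is_a: ", dag$parents[[id]]),
                 ""), con)
  }
  invisible(path)
}

#' Generate a null bundle (all planted effects off)
#'
#' @param config A [sim_config()]; its effect multipliers are reset via
#'   [null_config()] before simulation.
#' @return A `sim_bundle`.
#' @export
null_bundle <- function(config) {
  simulate_cohort(null_config(config))
}
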