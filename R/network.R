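#' Construct an annotated interaction network
#'
#' The central container: a node table of protein records (length, kinase
#' status, nuclear-localization-signal flag), per-protein annotation tables
#' (domains, disorder segments, PTM sites, GO terms, localization, clades),
#' the undirected edge set, and the identifiers of the 14-3-3 paralog hub
#' nodes present. Normally built via [assemble_full_network()].
#'
#' @param proteins data.frame with at least `protein_id` and `length`.
#' @param edges Undirected interaction table (`id_a`, `id_b`, `source`).
#' @param isoform_ids Named character vector label -> accession for the
#'   paralog hubs present in the network.
#' @param domains,disorder,ptms,go,localization,kinase_groups,clades
#'   Annotation tables restricted to network proteins (may be empty).
#' @return Object of class `annotated_network`.
#' @export
annotated_network <- function(proteins, edges, isoform_ids,
                              domains = empty_domains(),
                              disorder = empty_segments(),
                              ptms = NULL, go = NULL, localization = NULL,
                              kinase_groups = NULL, clades = NULL) {
  if (is.null(ptms))
    ptms <- data.frame(protein_id = character(0), position = integer(0),
                       residue = character(0), modification = character(0))
  if (is.null(go))
    go <- data.frame(protein_id = character(0), term_id = character(0))
  if (is.null(localization))
    localization <- data.frame(protein_id = character(0), label = character(0))
  if (is.null(kinase_groups))
    kinase_groups <- data.frame(protein_id = character(0), group = character(0))
  if (is.null(clades))
    clades <- data.frame(protein_id = character(0), clade_id = integer(0))
  stopifnot(all(c("protein_id", "length") %in% names(proteins)))
  endpoints <- unique(c(edges$id_a, edges$id_b))
  if (!all(endpoints %in% proteins$protein_id))
    stop("every edge endpoint must exist in the protein table")
  structure(list(proteins = proteins, edges = edges,
                 isoform_ids = isoform_ids, domains = domains,
                 disorder = disorder, ptms = ptms, go = go,
                 localization = localization, kinase_groups = kinase_groups,
                 clades = clades),
            class = "annotated_network")
}

#' Assemble the full 14-3-3 + kinase + substrate network
#'
#' Joins the deduplicated interaction list with the annotation bundle into an
#' [annotated_network()]. Protein length is taken from `lengths` when
#' supplied; otherwise the largest annotated coordinate (domain/disorder end
#' or PTM position) stands in for the unknown true length. Domain segments
#' extending beyond the known length are clipped with a warning.
#'
#' @param interactions Edge table from [read_interactions()].
#' @param annotations Bundle from [read_annotation_tables()].
#' @param ptms Site table from [read_ptm_table()] (optional).
#' @param isoform_id_map Named character vector label -> accession naming the
#'   seven 14-3-3 paralog hubs (default [isoform_accessions()]).
#' @param lengths Optional data.frame (`protein_id`, `length`).
#' @return An `annotated_network`; `summary()` reports node, edge and client
#'   counts (clients = distinct direct partners of any paralog hub).
#' @export
assemble_full_network <- function(interactions, annotations = NULL,
                                  ptms = NULL,
                                  isoform_id_map = isoform_accessions(),
                                  lengths = NULL) {
  edges <- normalize_edges(interactions)
  node_ids <- sort(unique(c(edges$id_a, edges$id_b)))
  missing_iso <- isoform_id_map[!isoform_id_map %in% node_ids]
  for (m in names(missing_iso))
    warning("isoform ", m, " (", missing_iso[[m]],
            ") absent from the interaction table")
  iso <- isoform_id_map[isoform_id_map %in% node_ids]

  if (is.null(annotations))
    annotations <- read_annotation_tables()
  dom <- annotations$domains
  dis <- annotations$disorder
  if (is.null(ptms))
    ptms <- validate_ptm_sites(data.frame(protein_id = character(0),
                                          position = integer(0),
                                          residue = character(0),
                                          modification = character(0)))
  restrict <- function(df) df[df$protein_id %in% node_ids, , drop = FALSE]
  dom <- restrict(dom); dis <- restrict(dis); ptms <- restrict(ptms)
  go <- restrict(annotations$go)
  loc <- restrict(annotations$localization)
  kg <- restrict(annotations$kinase_groups)
  cl <- restrict(annotations$clades)

  len <- stats::setNames(rep(NA_integer_, length(node_ids)), node_ids)
  if (!is.null(lengths)) {
    known <- lengths[lengths$protein_id %in% node_ids, , drop = FALSE]
    len[known$protein_id] <- as.integer(known$length)
  }
  unknown <- names(len)[is.na(len)]
  if (length(unknown) > 0L) {
    coord <- c(stats::setNames(dom$end, dom$protein_id),
               stats::setNames(dis$end, dis$protein_id),
               stats::setNames(ptms$position, ptms$protein_id))
    coord <- coord[names(coord) %in% unknown]
    if (length(coord) > 0L) {
      mx <- tapply(coord, names(coord), max)
      len[names(mx)] <- as.integer(mx)
    }
    len[is.na(len)] <- 1L
  }

  clip <- dom$end > len[dom$protein_id]
  if (any(clip)) {
    warning(sum(clip), " domain segment(s) clipped to protein length")
    dom$end[clip] <- len[dom$protein_id[clip]]
    dom <- dom[dom$start <= dom$end, , drop = FALSE]
  }
  dis$end <- pmin(dis$end, len[dis$protein_id])
  dis <- dis[dis$start <= dis$end, , drop = FALSE]
  ptms <- ptms[ptms$position <= len[ptms$protein_id], , drop = FALSE]

  proteins <- data.frame(protein_id = node_ids,
                         length = as.integer(len[node_ids]),
                         is_kinase = node_ids %in% kg$protein_id,
                         has_nls = node_ids %in%
                           dom$protein_id[dom$domain_name == "NLS"],
                         stringsAsFactors = FALSE)
  annotated_network(proteins, edges, iso, domains = dom, disorder = dis,
                    ptms = ptms, go = go, localization = loc,
                    kinase_groups = kg, clades = cl)
}

#' @export
summary.annotated_network <- function(object, ...) {
  hub <- unname(object$isoform_ids)
  partner_of_hub <- unique(c(
    object$edges$id_b[object$edges$id_a %in% hub],
    object$edges$id_a[object$edges$id_b %in% hub]))
  partner_of_hub <- setdiff(partner_of_hub, hub)
  out <- list(n_nodes = nrow(object$proteins),
              n_edges = nrow(object$edges),
              n_clients = length(partner_of_hub),
              isoforms = names(object$isoform_ids))
  class(out) <- "summary.annotated_network"
  out
}

#' @export
print.summary.annotated_network <- function(x, ...) {
  cat(sprintf("annotated network: %d nodes, %d edges, %d clients of %d paralog hub(s)\n",
              x$n_nodes, x$n_edges, x$n_clients, length(x$isoforms)))
  invisible(x)
}

#' @export
print.annotated_network <- function(x, ...) {
  print(summary(x))
  invisible(x)
}

#' Write a network to GraphML or TSV
#'
#' GraphML export carries, per node: protein length, kinase flag, NLS flag,
#' per-class PTM site counts, and one membership flag per 14-3-3 paralog;
#' per edge: provenance and (when the network has been oriented) direction
#' and posterior. `read_network(write_network(net))` reproduces the node set,
#' edge set and these exported attributes. TSV export writes the edge table
#' only.
#'
#' @param net An `annotated_network`.
#' @param path Output file.
#' @param format `"graphml"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.csv(net$edges, path, row.names = FALSE)
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(
    d = if (nrow(net$edges) > 0L) net$edges else
      data.frame(id_a = character(0), id_b = character(0)),
    directed = FALSE,
    vertices = data.frame(name = net$proteins$protein_id))
  if (nrow(net$proteins) > 0L) {
    igraph::V(g)$length <- net$proteins$length
    igraph::V(g)$is_kinase <- net$proteins$is_kinase
    igraph::V(g)$has_nls <- net$proteins$has_nls
    counts <- ptm_count_matrix(net)
    for (cls in colnames(counts))
      g <- igraph::set_vertex_attr(g, paste0("n_", cls),
                                   value = counts[net$proteins$protein_id,
                                                  cls])
    partner_sets <- lapply(net$isoform_ids, function(acc)
      hub_partners(net$edges, acc))
    for (lbl in names(partner_sets))
      g <- igraph::set_vertex_attr(g, paste0("partner_", lbl),
                                   value = net$proteins$protein_id %in%
                                     partner_sets[[lbl]])
  }
  g <- igraph::set_graph_attr(g, "isoform_labels",
                              paste(names(net$isoform_ids), collapse = ","))
  g <- igraph::set_graph_attr(g, "isoform_accessions",
                              paste(unname(net$isoform_ids), collapse = ","))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

# per-protein site counts by PTM class (pS, pT, pY, acK)
ptm_count_matrix <- function(net) {
  ids <- net$proteins$protein_id
  m <- matrix(0L, nrow = length(ids), ncol = 4,
              dimnames = list(ids, c("pS", "pT", "pY", "acK")))
  s <- net$ptms
  if (nrow(s) > 0L) {
    cls <- ptm_class(s)
    keep <- !is.na(cls)
    tab <- table(factor(s$protein_id[keep], levels = ids), cls[keep])
    m[rownames(tab), colnames(tab)] <- tab
  }
  m
}

# map a site table to pS/pT/pY/acK (NA for other modification types)
ptm_class <- function(sites) {
  out <- rep(NA_character_, nrow(sites))
  ph <- sites$modification == "phosphorylation"
  out[ph & sites$residue == "S"] <- "pS"
  out[ph & sites$residue == "T"] <- "pT"
  out[ph & sites$residue == "Y"] <- "pY"
  out[sites$modification == "acetylation" & sites$residue == "K"] <- "acK"
  out
}

hub_partners <- function(edges, hub_id) {
  setdiff(unique(c(edges$id_b[edges$id_a == hub_id],
                   edges$id_a[edges$id_b == hub_id])), hub_id)
}

#' Read a network from GraphML
#'
#' Inverse of [write_network()] for the exported attribute set. PTM counts
#' and paralog-membership flags come back as node-table columns; the detailed
#' site/domain tables are not representable in GraphML and are empty in the
#' returned object.
#'
#' @param path GraphML file written by [write_network()].
#' @return An `annotated_network`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- igraph::read_graph(path, format = "graphml")
  va <- igraph::vertex_attr_names(g)
  proteins <- data.frame(protein_id = igraph::V(g)$name,
                         stringsAsFactors = FALSE)
  for (a in setdiff(va, "name"))
    proteins[[a]] <- igraph::vertex_attr(g, a)
  if (!"length" %in% names(proteins))
    proteins$length <- rep(1L, nrow(proteins))
  proteins$length <- as.integer(proteins$length)
  el <- igraph::as_data_frame(g, what = "edges")
  names(el)[1:2] <- c("id_a", "id_b")
  edges <- normalize_edges(el)
  labels <- strsplit(igraph::graph_attr(g, "isoform_labels") %||% "", ",")[[1]]
  accs <- strsplit(igraph::graph_attr(g, "isoform_accessions") %||% "", ",")[[1]]
  iso <- stats::setNames(accs, labels)
  proteins <- proteins[order(proteins$protein_id), , drop = FALSE]
  rownames(proteins) <- NULL
  annotated_network(proteins, edges, iso)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1])) b else a
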