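#' Extract the subnetwork of one 14-3-3 paralog
#'
#' Partners are the direct neighbours of the paralog hub node. With
#' `include_kinase_layer = TRUE` the node set additionally contains every
#' kinase (or kinase substrate, i.e. any node carrying a kinase-adjacent
#' edge) adjacent to a partner, together with those edges; the induced edge
#' set is always a subset of the full network's edges.
#'
#' @param net An `annotated_network`.
#' @param isoform Isoform label present in `net$isoform_ids`.
#' @param include_kinase_layer Add the kinase/substrate hop (default TRUE).
#' @return Object of class `paralog_network`: list with `isoform`, `hub_id`,
#'   `partner_ids`, `node_ids`, `edges`, and a `net` back-reference used by
#'   annotation-driven analyses.
#' @export
extract_paralog_subnetwork <- function(net, isoform,
                                       include_kinase_layer = TRUE) {
  if (!isoform %in% names(net$isoform_ids))
    stop("unknown isoform '", isoform, "'; valid labels: ",
         paste(names(net$isoform_ids), collapse = ", "))
  hub <- unname(net$isoform_ids[[isoform]])
  partners <- hub_partners(net$edges, hub)
  nodes <- c(hub, partners)
  if (include_kinase_layer && length(partners) > 0L) {
    kin <- net$proteins$protein_id[net$proteins$is_kinase]
    touch_partner <- (net$edges$id_a %in% partners & net$edges$id_b %in% kin) |
      (net$edges$id_b %in% partners & net$edges$id_a %in% kin)
    kin_nodes <- unique(c(net$edges$id_a[touch_partner],
                          net$edges$id_b[touch_partner]))
    nodes <- unique(c(nodes, kin_nodes))
  }
  keep <- net$edges$id_a %in% nodes & net$edges$id_b %in% nodes
  structure(list(isoform = isoform, hub_id = hub,
                 partner_ids = sort(partners), node_ids = sort(unique(nodes)),
                 edges = net$edges[keep, , drop = FALSE], net = net),
            class = "paralog_network")
}

#' @export
print.paralog_network <- function(x, ...) {
  cat(sprintf("paralog network '%s': %d partners, %d nodes, %d edges\n",
              x$isoform, length(x$partner_ids), length(x$node_ids),
              nrow(x$edges)))
  invisible(x)
}

#' Extract all paralog subnetworks
#'
#' @inheritParams extract_paralog_subnetwork
#' @return Named list of `paralog_network` objects, one per isoform in `net`.
#' @export
paralog_subnetworks <- function(net, include_kinase_layer = TRUE) {
  labs <- names(net$isoform_ids)
  stats::setNames(lapply(labs, extract_paralog_subnetwork, net = net,
                         include_kinase_layer = include_kinase_layer), labs)
}

#' Jaccard similarity matrix of paralog partner sets
#'
#' |A intersect B| / |A union B| over the partner sets (direct neighbours of
#' each hub). The pair of two empty sets is defined as 0 and flagged.
#'
#' @param paralog_networks List of at least two `paralog_network` objects
#'   (or any named list with a `partner_ids` element).
#' @param use_node_sets Compare full node sets (with the kinase layer)
#'   instead of partner sets.
#' @return Symmetric numeric matrix with unit diagonal, class
#'   `jaccard_matrix`; attribute `degenerate_pairs` lists empty-vs-empty pairs.
#' @export
jaccard_matrix <- function(paralog_networks, use_node_sets = FALSE) {
  if (length(paralog_networks) < 2L) stop("need at least two paralog networks")
  labs <- vapply(paralog_networks, function(p) p$isoform, character(1))
  if (anyDuplicated(labs)) stop("duplicate isoform labels")
  sets <- lapply(paralog_networks, function(p)
    if (use_node_sets) setdiff(p$node_ids, p$hub_id) else p$partner_ids)
  k <- length(sets)
  m <- diag(1, k)
  dimnames(m) <- list(labs, labs)
  degenerate <- character(0)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    u <- length(union(sets[[i]], sets[[j]]))
    if (u == 0L) {
      m[i, j] <- m[j, i] <- 0
      degenerate <- c(degenerate, paste(labs[i], labs[j], sep = "-"))
    } else {
      m[i, j] <- m[j, i] <- length(intersect(sets[[i]], sets[[j]])) / u
    }
  }
  attr(m, "degenerate_pairs") <- degenerate
  class(m) <- c("jaccard_matrix", class(m))
  m
}

#' @export
print.jaccard_matrix <- function(x, digits = 3, ...) {
  print(round(unclass(x), digits))
  invisible(x)
}
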