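# Edge orientation: a hand-written categorical naive Bayes over an ordered
# node pair (a, b), trained on interactions of known direction (curated
# kinase -> substrate edges), used to turn the undirected interactome into a
# directed one for the motif census.

# Default feature schema for the ordered pair (a, b):
#   rel_degree : a's undirected degree vs b's (gt / lt / eq)
#   a_kinase, b_kinase : kinase flags
#   a_ptm, b_ptm : tercile bin of the node's total PTM site count
# Bin thresholds are computed on the training node pool and stored in the
# model; unseen categories at predict time map to a reserved level.
UNKNOWN_LEVEL <- ".unknown"

node_stats <- function(net) {
  ids <- net$proteins$protein_id
  deg <- stats::setNames(rep(0L, length(ids)), ids)
  tab <- table(c(net$edges$id_a, net$edges$id_b))
  deg[names(tab)] <- as.integer(tab)
  ptm <- stats::setNames(rep(0L, length(ids)), ids)
  if (nrow(net$ptms) > 0L) {
    pt <- table(net$ptms$protein_id)
    ptm[names(pt)] <- as.integer(pt)
  }
  data.frame(protein_id = ids, degree = unname(deg), is_kinase =
               net$proteins$is_kinase, ptm_count = unname(ptm),
             stringsAsFactors = FALSE)
}

ptm_breaks <- function(counts) {
  qs <- unique(stats::quantile(counts, c(1 / 3, 2 / 3), names = FALSE))
  c(-Inf, qs, Inf)
}

bin_counts <- function(counts, breaks) {
  labs <- c("low", "mid", "high")[seq_len(length(breaks) - 1L)]
  as.character(cut(counts, breaks = breaks, labels = labs,
                   include.lowest = TRUE))
}

#' Feature vectors for ordered node pairs
#'
#' @param net An `annotated_network`.
#' @param id_a,id_b Equal-length accession vectors; features describe the
#'   ordered pair (a, b).
#' @param breaks Bin boundaries for the PTM-count terciles (default: computed
#'   from all nodes of `net`).
#' @return data.frame of categorical features (one row per pair).
#' @export
edge_features <- function(net, id_a, id_b, breaks = NULL) {
  ns <- node_stats(net)
  rownames(ns) <- ns$protein_id
  if (is.null(breaks)) breaks <- ptm_breaks(ns$ptm_count)
  da <- ns[id_a, "degree"]; db <- ns[id_b, "degree"]
  data.frame(
    rel_degree = ifelse(da > db, "gt", ifelse(da < db, "lt", "eq")),
    a_kinase = as.character(ns[id_a, "is_kinase"]),
    b_kinase = as.character(ns[id_b, "is_kinase"]),
    a_ptm = bin_counts(ns[id_a, "ptm_count"], breaks),
    b_ptm = bin_counts(ns[id_b, "ptm_count"], breaks),
    stringsAsFactors = FALSE)
}

#' Train a naive Bayes direction classifier
#'
#' Categorical naive Bayes with add-alpha (Laplace) smoothing: the
#' conditional probability of level l of feature f given class c is
#' (count + alpha) / (n_c + alpha * K_f), with K_f the number of levels of f
#' including the reserved unseen level. Class priors are maximum-likelihood.
#'
#' @param features data.frame of categorical features (as from
#'   [edge_features()]).
#' @param labels Character/factor vector of class labels (`forward` =
#'   direction a to b, `reverse` = b to a); both classes must occur.
#' @param alpha Smoothing constant (default 1).
#' @return Object of class `naive_bayes_model`.
#' @export
train_naive_bayes <- function(features, labels, alpha = 1) {
  if (nrow(features) == 0L) stop("empty training set")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop("training set contains a single class; cannot calibrate")
  priors <- table(factor(labels, classes)) / length(labels)
  cond <- lapply(features, function(col) {
    col <- as.character(col)
    levels <- c(sort(unique(col)), UNKNOWN_LEVEL)
    tab <- table(factor(col, levels), factor(labels, classes))
    probs <- sweep(tab + alpha, 2, colSums(tab) + alpha * length(levels), "/")
    probs
  })
  structure(list(priors = as.numeric(priors), classes = classes,
                 conditionals = cond, alpha = alpha,
                 feature_names = names(features)),
            class = "naive_bayes_model")
}

#' @export
print.naive_bayes_model <- function(x, ...) {
  cat(sprintf("naive Bayes direction model: %d features, alpha = %g\n",
              length(x$conditionals), x$alpha))
  invisible(x)
}

#' Predict the orientation of ordered node pairs
#'
#' Posteriors over \{forward, reverse\} are normalized per pair; the
#' orientation is the argmax. Exact posterior ties are broken toward the
#' lexicographically smaller source identifier and flagged.
#'
#' @param model A `naive_bayes_model`.
#' @param features data.frame with the model's feature schema.
#' @param id_a,id_b Pair identifiers (needed only for tie-breaking; default
#'   breaks ties toward `forward`).
#' @return data.frame with `orientation`, `posterior` (of the chosen
#'   orientation), `p_forward`, and `tie`.
#' @export
predict_direction <- function(model, features, id_a = NULL, id_b = NULL) {
  miss <- setdiff(model$feature_names, names(features))
  if (length(miss) > 0L)
    stop("feature schema mismatch: missing feature(s) ",
         paste(miss, collapse = ", "))
  n <- nrow(features)
  logp <- matrix(rep(log(model$priors), each = n), nrow = n)
  for (f in model$feature_names) {
    probs <- model$conditionals[[f]]
    lev <- as.character(features[[f]])
    lev[!lev %in% rownames(probs)] <- UNKNOWN_LEVEL
    logp <- logp + log(probs[lev, , drop = FALSE])
  }
  logp <- logp - apply(logp, 1, max)
  post <- exp(logp) / rowSums(exp(logp))
  colnames(post) <- model$classes
  p_fwd <- post[, "forward"]
  tie <- abs(p_fwd - 0.5) < 1e-12
  forward <- p_fwd > 0.5
  if (any(tie)) {
    prefer_fwd <- if (is.null(id_a)) rep(TRUE, n) else id_a <= id_b
    forward[tie] <- prefer_fwd[tie]
  }
  data.frame(orientation = ifelse(forward, "forward", "reverse"),
             posterior = ifelse(forward, p_fwd, 1 - p_fwd),
             p_forward = p_fwd, tie = tie, stringsAsFactors = FALSE)
}

#' Train the direction classifier from curated directed edges
#'
#' Builds one `forward` and one `reverse` instance per known directed edge
#' (both orderings), computes the PTM-count bin thresholds on the training
#' node pool, and trains [train_naive_bayes()].
#'
#' @param net An `annotated_network`.
#' @param train_edges data.frame (`from`, `to`) of curated directed edges,
#'   e.g. kinase to substrate.
#' @param alpha Smoothing constant.
#' @return `naive_bayes_model` with the bin `breaks` attached.
#' @export
train_edge_classifier <- function(net, train_edges, alpha = 1) {
  if (nrow(train_edges) == 0L) stop("empty training set")
  ns <- node_stats(net)
  breaks <- ptm_breaks(ns$ptm_count[ns$protein_id %in%
                                      c(train_edges$from, train_edges$to)])
  fwd <- edge_features(net, train_edges$from, train_edges$to, breaks)
  rev <- edge_features(net, train_edges$to, train_edges$from, breaks)
  model <- train_naive_bayes(rbind(fwd, rev),
                             rep(c("forward", "reverse"),
                                 each = nrow(train_edges)), alpha)
  model$breaks <- breaks
  model
}

#' Orient every edge of a network
#'
#' Assigns each undirected edge exactly one direction plus the classifier
#' posterior. Curated directed edges (the training pairs) keep their known
#' direction when `override = TRUE` (default), regardless of the classifier.
#'
#' @param net An `annotated_network`.
#' @param model Model from [train_edge_classifier()].
#' @param curated Optional data.frame (`from`, `to`) of edges with known
#'   direction.
#' @param override Keep curated directions (default TRUE).
#' @return `net` with edge columns `direction` (`"ab"`/`"ba"` relative to the
#'   canonical `id_a < id_b` ordering), `posterior`, and `curated`.
#' @export
orient_network <- function(net, model, curated = NULL, override = TRUE) {
  edges <- net$edges
  if (nrow(edges) > 0L) {
    pred <- predict_direction(model,
                              edge_features(net, edges$id_a, edges$id_b,
                                            model$breaks),
                              edges$id_a, edges$id_b)
    edges$direction <- ifelse(pred$orientation == "forward", "ab", "ba")
    edges$posterior <- pred$posterior
    edges$curated <- FALSE
    if (!is.null(curated) && override && nrow(curated) > 0L) {
      key <- paste(pmin(curated$from, curated$to),
                   pmax(curated$from, curated$to), sep = "\r")
      ekey <- paste(edges$id_a, edges$id_b, sep = "\r")
      hit <- match(ekey, key)
      is_cur <- !is.na(hit)
      edges$curated[is_cur] <- TRUE
      edges$direction[is_cur] <-
        ifelse(curated$from[hit[is_cur]] == edges$id_a[is_cur], "ab", "ba")
    }
  } else {
    edges$direction <- character(0)
    edges$posterior <- numeric(0)
    edges$curated <- logical(0)
  }
  net$edges <- edges
  class(net) <- unique(c("oriented_network", class(net)))
  net
}

#' Directed edge list of an oriented network
#'
#' @param net An oriented `annotated_network` (from [orient_network()]) or
#'   any data.frame with `from`/`to` columns.
#' @return data.frame (`from`, `to`).
#' @export
directed_edgelist <- function(net) {
  if (is.data.frame(net)) {
    stopifnot(all(c("from", "to") %in% names(net)))
    return(net[, c("from", "to")])
  }
  e <- net$edges
  if (is.null(e$direction)) stop("network has not been oriented")
  data.frame(from = ifelse(e$direction == "ab", e$id_a, e$id_b),
             to = ifelse(e$direction == "ab", e$id_b, e$id_a),
             stringsAsFactors = FALSE)
}
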