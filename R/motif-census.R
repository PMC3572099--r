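# Directed 3-node motif census against the 13-class connected-triad
# dictionary (Alon numbering), with a degree-preserving switching null model.
#
# Bit layout of a triad adjacency mask over ordered node slots (1,2,3):
#   bit 0: 1->2, bit 1: 1->3, bit 2: 2->1, bit 3: 2->3, bit 4: 3->1, bit 5: 3->2

.paralognet_env <- new.env(parent = emptyenv())

BITPOS <- matrix(c(NA, 0L, 1L,
                   2L, NA, 3L,
                   4L, 5L, NA), nrow = 3, byrow = TRUE)

PERMS3 <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

TRIAD_NAMES <- c(
  "divergence (021D)",                     # 1
  "convergence (021U)",                    # 2
  "chain (021C)",                          # 3
  "mutual dyad with incoming edge (111D)", # 4
  "mutual dyad with outgoing edge (111U)", # 5
  "three-node cycle (030C)",               # 6
  "feed-forward loop (030T)",              # 7
  "two mutual dyads (201)",                # 8
  "mutual pair regulated by a third (120)",      # 9
  "mutual pair co-regulating a third (120)",     # 10
  "mutual pair with through-flow (120C)",  # 11
  "five-edge triad (210)",                 # 12
  "complete triad (300)")                  # 13

mask_from_pairs <- function(pairs) {
  m <- 0L
  if (length(pairs) > 0L)
    for (p in pairs) m <- bitwOr(m, bitwShiftL(1L, BITPOS[p[1], p[2]]))
  m
}

mask_is_connected <- function(mask) {
  und <- c(bitwAnd(mask, 1L + 4L) > 0L,    # 1-2
           bitwAnd(mask, 2L + 16L) > 0L,   # 1-3
           bitwAnd(mask, 8L + 32L) > 0L)   # 2-3
  sum(und) >= 2L
}

permute_mask <- function(mask, perm) {
  out <- 0L
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    if (bitwAnd(mask, bitwShiftL(1L, BITPOS[i, j])) > 0L)
      out <- bitwOr(out, bitwShiftL(1L, BITPOS[perm[i], perm[j]]))
  }
  out
}

# Representative edge sets defining dictionary IDs 1..13. IDs 3 (chain),
# 7 (feed-forward loop) and 10 (mutual pair co-regulating a third) are fixed
# by their published descriptions; the remaining order follows the standard
# dictionary layout (single-edge-type triads, mutual-dyad triads, two-edge-
# type triads, then increasing density).
triad_representatives <- function() {
  list(
    list(c(2, 1), c(2, 3)),                                  # 1  021D
    list(c(1, 2), c(3, 2)),                                  # 2  021U
    list(c(1, 2), c(2, 3)),                                  # 3  021C chain
    list(c(1, 2), c(2, 1), c(3, 1)),                         # 4  111D
    list(c(1, 2), c(2, 1), c(1, 3)),                         # 5  111U
    list(c(1, 2), c(2, 3), c(3, 1)),                         # 6  030C
    list(c(1, 2), c(1, 3), c(2, 3)),                         # 7  030T FFL
    list(c(1, 2), c(2, 1), c(1, 3), c(3, 1)),                # 8  201
    list(c(1, 2), c(2, 1), c(3, 1), c(3, 2)),                # 9  120 regulated
    list(c(1, 2), c(2, 1), c(1, 3), c(2, 3)),                # 10 120 co-reg
    list(c(1, 2), c(2, 1), c(3, 1), c(2, 3)),                # 11 120C
    list(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3)),       # 12 210
    list(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2)) # 13 300
  )
}

#' The 13-class connected-triad dictionary
#'
#' Builds (once per session) the lookup from each of the 64 possible 3-node
#' directed adjacency masks to its dictionary ID (1-13; 0 for weakly
#' disconnected masks), and self-validates: exactly 13 connected isomorphism
#' classes, class sizes summing to the number of connected masks, and the
#' three anchor topologies (3 = linear chain, 7 = feed-forward loop,
#' 10 = mutual pair co-regulating a third) matching their definitions.
#'
#' @return List with `class_of_mask` (length 64, for masks 0..63),
#'   `canonical_of_mask`, and `names`.
#' @export
triad_dictionary <- function() {
  if (!is.null(.paralognet_env$triad_dict)) return(.paralognet_env$triad_dict)
  masks <- 0:63
  canonical <- vapply(masks, function(m)
    min(vapply(seq_len(nrow(PERMS3)), function(k)
      permute_mask(m, PERMS3[k, ]), integer(1))), integer(1))
  connected <- vapply(masks, mask_is_connected, logical(1))
  reps <- triad_representatives()
  rep_canon <- vapply(reps, function(r)
    canonical[mask_from_pairs(r) + 1L], integer(1))
  stopifnot(!anyDuplicated(rep_canon))
  class_of_mask <- integer(64)
  for (id in seq_along(rep_canon))
    class_of_mask[connected & canonical == rep_canon[id]] <- id
  # internal validation
  stopifnot(length(unique(canonical[connected])) == 13L,
            all(sort(unique(canonical[connected])) == sort(rep_canon)),
            sum(class_of_mask > 0L) == sum(connected),
            class_of_mask[mask_from_pairs(list(c(1, 2), c(2, 3))) + 1L] == 3L,
            class_of_mask[mask_from_pairs(list(c(1, 2), c(1, 3), c(2, 3))) + 1L] == 7L,
            class_of_mask[mask_from_pairs(list(c(1, 2), c(2, 1), c(1, 3),
                                               c(2, 3))) + 1L] == 10L)
  dict <- list(class_of_mask = class_of_mask, canonical_of_mask = canonical,
               names = TRIAD_NAMES)
  .paralognet_env$triad_dict <- dict
  dict
}

#' Classify one directed triad
#'
#' @param edges data.frame (`from`, `to`) or 2-column matrix of directed
#'   edges among at most three labelled nodes.
#' @param nodes Optional vector of exactly three node labels (needed when
#'   some node is isolated).
#' @return Dictionary ID (integer 1-13) or the string `"disconnected"`.
#' @export
classify_triad <- function(edges, nodes = NULL) {
  if (is.matrix(edges)) edges <- data.frame(from = edges[, 1], to = edges[, 2])
  labels <- unique(c(as.character(edges$from), as.character(edges$to),
                     as.character(nodes)))
  if (length(labels) > 3L) stop("a triad has exactly three nodes")
  if (length(labels) < 3L) {
    if (is.null(nodes)) stop("supply `nodes` when fewer than 3 appear in edges")
    return("disconnected")
  }
  idx <- stats::setNames(1:3, sort(labels))
  pairs <- Map(function(f, t) c(idx[[f]], idx[[t]]),
               as.character(edges$from), as.character(edges$to))
  if (any(vapply(pairs, function(p) p[1] == p[2], logical(1))))
    stop("self-loops are not allowed in a triad")
  cls <- triad_dictionary()$class_of_mask[mask_from_pairs(unname(pairs)) + 1L]
  if (cls == 0L) "disconnected" else cls
}

#' Census of connected directed triads
#'
#' Counts every weakly connected unordered node triple exactly once and
#' classifies it against [triad_dictionary()].
#'
#' @param edges Directed edge list: data.frame (`from`, `to`); self-loops are
#'   an error. Parallel duplicate edges are collapsed.
#' @param nodes Optional full node label vector (isolated nodes do not affect
#'   the census).
#' @return Object of class `triad_census`: named integer vector of per-class
#'   counts (`"1"`..`"13"`) with attribute `total`.
#' @export
enumerate_triads <- function(edges, nodes = NULL) {
  edges <- as_directed_edges(edges)
  labels <- sort(unique(c(edges$from, edges$to, as.character(nodes))))
  f <- match(edges$from, labels) - 1L
  t <- match(edges$to, labels) - 1L
  counts <- cpp_triad_census(f, t, length(labels),
                             triad_dictionary()$class_of_mask)
  out <- stats::setNames(as.integer(counts), as.character(1:13))
  attr(out, "total") <- sum(counts)
  class(out) <- "triad_census"
  out
}

as_directed_edges <- function(edges) {
  if (is.matrix(edges)) edges <- data.frame(from = edges[, 1], to = edges[, 2])
  stopifnot(all(c("from", "to") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  edges[!duplicated(paste(edges$from, edges$to, sep = "\r")), , drop = FALSE]
}

#' @export
print.triad_census <- function(x, ...) {
  cat("triad census (", attr(x, "total"), " connected triples):\n", sep = "")
  print(unclass(x)[unclass(x) > 0])
  invisible(x)
}

#' Degree-preserving randomization of a directed network
#'
#' Switching (double-edge swap) null model: unidirectional edges and
#' reciprocal pairs are rewired within their own subsets, so every node's
#' in-degree and out-degree and the number of reciprocal edges are preserved
#' exactly, and no self-loops or multi-edges are introduced.
#'
#' @param edges Directed edge list (`from`, `to`).
#' @param n_swaps_per_edge Successful swaps per edge, Q (default 10).
#' @param seed Optional integer seed (local to this call).
#' @param nodes Optional full node label vector.
#' @return Randomized edge list with attribute `swaps` (performed) and
#'   `target`; a warning is raised when the network is too rigid to reach
#'   the target.
#' @export
randomize_directed <- function(edges, n_swaps_per_edge = 10, seed = NULL,
                               nodes = NULL) {
  if (n_swaps_per_edge < 1) stop("n_swaps_per_edge must be >= 1")
  edges <- as_directed_edges(edges)
  labels <- sort(unique(c(edges$from, edges$to, as.character(nodes))))
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  res <- cpp_switch_randomize(match(edges$from, labels) - 1L,
                              match(edges$to, labels) - 1L,
                              length(labels), n_swaps_per_edge, 200L)
  if (res$swaps < res$target)
    warning(sprintf("network too rigid: %d of %d target swaps performed",
                    as.integer(res$swaps), as.integer(res$target)))
  out <- data.frame(from = labels[res$from + 1L], to = labels[res$to + 1L],
                    stringsAsFactors = FALSE)
  attr(out, "swaps") <- res$swaps
  attr(out, "target") <- res$target
  out
}

#' Motif enrichment against a randomized ensemble
#'
#' Compares the observed triad census with `ensemble_size` degree-preserving
#' randomizations. Per class: ensemble mean and sd, z-score (NA, flagged,
#' when sd = 0), and the one-sided empirical enrichment p-value
#' (1 + #\{random >= observed\}) / (ensemble_size + 1), never zero.
#'
#' @param edges Directed edge list (`from`, `to`).
#' @param ensemble_size Number of randomized networks, R (default 1000).
#' @param n_swaps_per_edge Q for [randomize_directed()] (default 10).
#' @param seed Integer seed for the ensemble (local to this call).
#' @param alpha Enrichment flag threshold on the empirical p (default 0.05).
#' @return data.frame of class `motif_significance`: `class_id`, `name`,
#'   `count`, `mean_rand`, `sd_rand`, `z`, `p`, `enriched`; attributes
#'   `ensemble_size`, `seed`.
#' @export
motif_significance <- function(edges, ensemble_size = 1000,
                               n_swaps_per_edge = 10, seed = NULL,
                               alpha = 0.05) {
  if (ensemble_size < 1) stop("ensemble_size must be >= 1")
  edges <- as_directed_edges(edges)
  labels <- sort(unique(c(edges$from, edges$to)))
  f <- match(edges$from, labels) - 1L
  t <- match(edges$to, labels) - 1L
  dict <- triad_dictionary()$class_of_mask
  real <- as.integer(cpp_triad_census(f, t, length(labels), dict))
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  rand <- matrix(0L, nrow = ensemble_size, ncol = 13)
  short <- 0L
  for (r in seq_len(ensemble_size)) {
    rw <- cpp_switch_randomize(f, t, length(labels), n_swaps_per_edge, 200L)
    if (rw$swaps < rw$target) short <- short + 1L
    rand[r, ] <- as.integer(cpp_triad_census(rw$from, rw$to, length(labels),
                                             dict))
  }
  if (short > 0L)
    warning(short, " randomization(s) did not reach the swap target")
  mu <- colMeans(rand)
  sdv <- apply(rand, 2, stats::sd)
  z <- ifelse(sdv > 0, (real - mu) / sdv, NA_real_)
  p <- (1 + colSums(rand >= matrix(real, nrow = ensemble_size, ncol = 13,
                                   byrow = TRUE))) / (ensemble_size + 1)
  out <- data.frame(class_id = 1:13, name = TRIAD_NAMES, count = real,
                    mean_rand = mu, sd_rand = sdv, z = z, p = p,
                    enriched = p < alpha, stringsAsFactors = FALSE)
  attr(out, "ensemble_size") <- ensemble_size
  attr(out, "seed") <- seed
  class(out) <- c("motif_significance", class(out))
  out
}
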