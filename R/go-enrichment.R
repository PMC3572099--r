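# Over-representation analysis on a Gene Ontology DAG: OBO parsing,
# true-path annotation propagation, hypergeometric tests, BH adjustment,
# adaptive thresholding, and cross-isoform -log10 p comparison.

#' Parse an OBO v1.2 ontology file
#'
#' Minimal stanza parser retaining term id, name, namespace, `is_a` parents
#' and (optionally, off by default) `part_of` relationships. Obsolete terms
#' are dropped with their count recorded.
#'
#' @param path OBO file.
#' @param include_part_of Also traverse `relationship: part_of` edges
#'   (default FALSE).
#' @return Object of class `ontology_dag`: list with `terms` (data.frame
#'   `term_id`, `name`, `namespace`), `parents` (named list child -> parent
#'   ids), `n_obsolete`.
#' @export
read_obo <- function(path, include_part_of = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  ends <- c(starts[-1] - 1L, length(lines))
  ids <- names <- namespaces <- character(0)
  parents <- list()
  n_obsolete <- 0L
  field <- function(block, key) {
    hits <- grep(paste0("^", key, ": "), block, value = TRUE)
    sub("\\s*!.*$", "", sub(paste0("^", key, ": "), "", hits))
  }
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    id <- field(block, "id")[1]
    if (is.na(id) || !nzchar(id)) next
    if (any(field(block, "is_obsolete") == "true")) {
      n_obsolete <- n_obsolete + 1L
      next
    }
    par <- field(block, "is_a")
    if (include_part_of) {
      rel <- field(block, "relationship")
      par <- c(par, sub("^part_of ", "", rel[grepl("^part_of ", rel)]))
    }
    ids <- c(ids, id)
    names <- c(names, field(block, "name")[1] %||% id)
    namespaces <- c(namespaces, field(block, "namespace")[1] %||% NA_character_)
    parents[[id]] <- trimws(par)
  }
  dag <- structure(list(
    terms = data.frame(term_id = ids, name = names, namespace = namespaces,
                       stringsAsFactors = FALSE),
    parents = parents, n_obsolete = n_obsolete),
    class = "ontology_dag")
  validate_dag(dag)
  dag
}

#' Build an ontology DAG from tables (used by the synthetic generator)
#'
#' @param terms data.frame (`term_id`, `name`, `namespace`).
#' @param parent_edges data.frame (`term_id`, `parent_id`) of is_a edges.
#' @return `ontology_dag`.
#' @export
ontology_dag <- function(terms, parent_edges) {
  parents <- split(parent_edges$parent_id, parent_edges$term_id)
  parents <- parents[intersect(terms$term_id, names(parents))]
  dag <- structure(list(terms = terms, parents = parents, n_obsolete = 0L),
                   class = "ontology_dag")
  validate_dag(dag)
  dag
}

validate_dag <- function(dag) {
  anc <- term_ancestors(dag)
  for (id in names(anc))
    if (id %in% anc[[id]]) stop("ontology contains a cycle through ", id)
  invisible(TRUE)
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("ontology: %d terms (%s); %d obsolete dropped\n",
              nrow(x$terms),
              paste(names(table(x$terms$namespace)), collapse = ", "),
              x$n_obsolete))
  invisible(x)
}

# memoized map term -> all ancestors (excluding self), set semantics
term_ancestors <- function(dag) {
  anc <- new.env(parent = emptyenv())
  get_anc <- function(id, seen = character(0)) {
    if (!is.null(anc[[id]])) return(anc[[id]])
    if (id %in% seen) stop("ontology contains a cycle through ", id)
    par <- dag$parents[[id]]
    par <- par[par %in% dag$terms$term_id]
    res <- unique(c(par, unlist(lapply(par, get_anc, seen = c(seen, id)))))
    anc[[id]] <- res
    res
  }
  out <- lapply(dag$terms$term_id, get_anc)
  stats::setNames(out, dag$terms$term_id)
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' Every protein directly annotated to a term is implicitly annotated to all
#' of the term's ancestors; ancestors reached via several paths count once.
#' Direct terms missing from the DAG are kept as direct-only and logged.
#'
#' @param annotations data.frame (`protein_id`, `term_id`) of direct
#'   annotations.
#' @param dag An `ontology_dag`.
#' @return data.frame (`protein_id`, `term_id`) including propagated rows;
#'   attribute `n_unknown_terms`.
#' @export
propagate_annotations <- function(annotations, dag) {
  anc <- term_ancestors(dag)
  known <- annotations$term_id %in% names(anc)
  extra <- NULL
  if (any(known)) {
    a <- annotations[known, , drop = FALSE]
    ancestor_lists <- anc[a$term_id]
    reps <- lengths(ancestor_lists)
    extra <- data.frame(protein_id = rep(a$protein_id, reps),
                        term_id = unlist(ancestor_lists, use.names = FALSE),
                        stringsAsFactors = FALSE)
  }
  out <- unique(rbind(annotations, extra))
  out <- out[order(out$protein_id, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unknown_terms") <- length(unique(annotations$term_id[!known]))
  out
}

#' Hypergeometric term over-representation
#'
#' For every term of the namespace annotating at least one universe protein
#' (after true-path propagation): upper-tail hypergeometric p of observing
#' `k` annotated query proteins given `K` annotated among the `N`-protein
#' universe, plus Benjamini-Hochberg q over all tested terms.
#'
#' @param query Character vector of protein ids (subset of `universe`).
#' @param universe Character vector of protein ids (default: all annotated
#'   proteins); the paper's comparison universe is the full assembled
#'   network's node set.
#' @param annotations Direct annotations (`protein_id`, `term_id`).
#' @param dag An `ontology_dag`.
#' @param namespace Restrict to one namespace (e.g. `"biological_process"`);
#'   NULL for all.
#' @return data.frame of class `enrichment_result`: `term_id`, `name`,
#'   `namespace`, `k`, `n`, `K`, `N`, `p`, `q`, sorted by p.
#' @export
enrich <- function(query, universe = NULL, annotations, dag,
                   namespace = NULL) {
  query <- unique(query)
  if (length(query) == 0L) stop("empty query set")
  if (is.null(universe)) universe <- unique(annotations$protein_id)
  universe <- unique(universe)
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  ann <- propagate_annotations(annotations, dag)
  ann <- ann[ann$protein_id %in% universe, , drop = FALSE]
  if (!is.null(namespace)) {
    keep <- dag$terms$term_id[dag$terms$namespace == namespace]
    ann <- ann[ann$term_id %in% keep, , drop = FALSE]
  }
  if (nrow(ann) == 0L)
    return(empty_enrichment())
  by_term <- split(ann$protein_id, ann$term_id)
  K <- lengths(by_term)
  k <- vapply(by_term, function(p) sum(p %in% query), integer(1))
  N <- length(universe)
  n <- length(query)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  info <- dag$terms[match(names(by_term), dag$terms$term_id), , drop = FALSE]
  out <- data.frame(term_id = names(by_term), name = info$name,
                    namespace = info$namespace,
                    k = k, n = n, K = as.integer(K), N = N, p = p,
                    q = benjamini_hochberg(p), stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", class(out))
  out
}

empty_enrichment <- function() {
  out <- data.frame(term_id = character(0), name = character(0),
                    namespace = character(0), k = integer(0), n = integer(0),
                    K = integer(0), N = integer(0), p = numeric(0),
                    q = numeric(0))
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Adaptive p-value threshold for a target term count
#'
#' Chooses the largest observed-p cutoff whose retained set size falls in
#' `[lo, hi]` (the report-graph sizing rule); when no cutoff achieves a size
#' in range, the nearest achievable size is used with a warning.
#'
#' @param results An `enrichment_result`.
#' @param lo,hi Target range of retained terms (defaults 35 and 50).
#' @return List with `cutoff`, `retained` (subset of `results`), `achieved`.
#' @export
adaptive_threshold <- function(results, lo = 35, hi = 50) {
  if (lo > hi) stop("lo must not exceed hi")
  if (nrow(results) == 0L) stop("no enrichment results")
  ps <- sort(unique(results$p))
  sizes <- vapply(ps, function(c) sum(results$p <= c), integer(1))
  ok <- sizes >= lo & sizes <= hi
  if (any(ok)) {
    cutoff <- max(ps[ok])
  } else {
    best <- which.min(pmax(lo - sizes, sizes - hi, 0))
    cutoff <- ps[best]
    warning(sprintf("no cutoff yields %d-%d terms; nearest achievable size is %d",
                    lo, hi, sizes[best]))
  }
  retained <- results[results$p <= cutoff, , drop = FALSE]
  list(cutoff = cutoff, retained = retained, achieved = nrow(retained))
}

#' Cross-isoform -log10 p comparison matrix
#'
#' For a list of per-network enrichment results and a term list: the matrix
#' of -log10 p for cells significant at `alpha`; non-significant or untested
#' cells are 0, with a parallel status matrix distinguishing
#' `"significant"`, `"not_significant"` and `"untested"`.
#'
#' @param results_list Named list of `enrichment_result`s (same universe).
#' @param terms Term ids (rows of interest).
#' @param alpha Significance threshold on raw p (default 0.05).
#' @return List with `neg_log10_p` (isoform x term) and `status`.
#' @export
compare_enrichment <- function(results_list, terms, alpha = 0.05) {
  labs <- names(results_list)
  m <- matrix(0, length(labs), length(terms), dimnames = list(labs, terms))
  status <- matrix("untested", length(labs), length(terms),
                   dimnames = list(labs, terms))
  for (l in labs) {
    res <- results_list[[l]]
    idx <- match(terms, res$term_id)
    tested <- !is.na(idx)
    sig <- tested & res$p[idx] < alpha
    status[l, tested] <- "not_significant"
    status[l, sig] <- "significant"
    m[l, sig] <- -log10(res$p[idx[sig]])
  }
  list(neg_log10_p = m, status = status)
}
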