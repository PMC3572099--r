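# Independent brute-force oracles used to validate the statistical kernels.
# These deliberately avoid the code paths they check.

# Two-sided Fisher p by full enumeration over all tables with the observed
# margins: sum the point hypergeometric probabilities not exceeding the
# observed one (relative tolerance 1e-7).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  x <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, x) * choose(r2, c1 - x) / choose(r1 + r2, c1)
  pobs <- choose(r1, a) * choose(r2, c) / choose(r1 + r2, c1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Upper-tail hypergeometric P(X >= k) by direct summation of binomial
# coefficients.
hyper_tail_oracle <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Exact two-sided Wilcoxon rank-sum p by enumeration of all rank
# assignments (small samples, no ties).
wilcoxon_oracle <- function(a, b) {
  na <- length(a)
  ranks <- rank(c(a, b))
  obs <- sum(ranks[seq_len(na)])
  all_sums <- combn(seq_len(na + length(b)), na, sum)
  mu <- mean(all_sums)
  min(1, mean(abs(all_sums - mu) >= abs(obs - mu) - 1e-9))
}

# Exhaustive triad census: classify every C(n,3) node triple.
census_oracle <- function(edges, nodes) {
  counts <- stats::setNames(rep(0L, 13), as.character(1:13))
  for (tr in combn(nodes, 3, simplify = FALSE)) {
    sel <- edges$from %in% tr & edges$to %in% tr
    cl <- classify_triad(edges[sel, , drop = FALSE], nodes = tr)
    if (!identical(cl, "disconnected"))
      counts[as.character(cl)] <- counts[as.character(cl)] + 1L
  }
  counts
}

random_digraph <- function(n, p = 0.25) {
  m <- matrix(stats::runif(n * n) < p, n, n)
  diag(m) <- FALSE
  el <- which(m, arr.ind = TRUE)
  if (nrow(el) == 0L)
    return(data.frame(from = character(0), to = character(0)))
  data.frame(from = paste0("n", el[, 1]), to = paste0("n", el[, 2]),
             stringsAsFactors = FALSE)
}
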