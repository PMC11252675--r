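# Independent oracles used across the suite.  These deliberately avoid the
# package's reduced-state machinery: the full-state master equation is built
# directly on all 2^N frozen subsets.

# Full (unreduced) generator on the 2^N subsets of an adjacency list.
full_generator <- function(n, adj, alpha) {
  m <- 2^n
  bit <- 2^(0:(n - 1))
  Q <- matrix(0, m, m)
  for (mask in 0:(m - 1)) {
    frozen <- which(bitwAnd(mask, bit) != 0)
    for (j in setdiff(seq_len(n), frozen)) {
      k <- sum(adj[[j]] %in% frozen)
      Q[mask + 1, mask + bit[j] + 1] <- 1 + k * alpha
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# Probabilities of every raw subset at the requested tau values.
full_master_solution <- function(n, adj, alpha, tau_grid, start_mask = 0) {
  Q <- full_generator(n, adj, alpha)
  p0 <- numeric(2^n)
  p0[start_mask + 1] <- 1
  t(vapply(tau_grid, function(tt)
    as.numeric(p0 %*% as.matrix(Matrix::expm(Q * tt))),
    numeric(2^n)))
}

adj_from_graph <- function(graph) adjacency_list(graph)

# Deterministic pseudo-random connected-ish graph on n cells.
random_test_graph <- function(n, p = 0.5, seed = 1) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  # ensure no isolated chain-breaking: add a spanning path
  edges <- rbind(pairs[keep, , drop = FALSE], cbind(1:(n - 1), 2:n))
  contact_graph(n, edges)
}

# Rat hepatocyte defaults shared by the biophysics tests.
hep <- rat_hepatocyte()
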