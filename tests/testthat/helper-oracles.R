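# Independent dense oracles and small random-instance builders used
# across the suite. These deliberately avoid the package's sparse code
# paths: plain base-R matrices, double loops, brute-force scans.

`%or%` <- function(a, b) if (is.null(a)) b else a

# Dense affinity by pairwise scan over the raw edge rows.
oracle_affinity <- function(nodes, edges_df, assignments, lambda) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges_df))) {
    a <- as.character(edges_df[[1L]][r])
    b <- as.character(edges_df[[2L]][r])
    if (a == b) next
    da <- assignments[[a]] %or% character(0)
    db <- assignments[[b]] %or% character(0)
    w <- if (length(intersect(da, db)) > 0L) lambda else 1
    A[a, b] <- w
    A[b, a] <- w
  }
  A
}

oracle_transition <- function(A) sweep(A, 1L, rowSums(A), "/")

# Explicit dense power: materialize M^t then multiply once.
oracle_power_apply <- function(M, X, t) {
  P <- diag(nrow(M))
  for (k in seq_len(t)) P <- P %*% M
  P %*% as.matrix(X)
}

# Random undirected edge table over a label alphabet (may contain
# duplicates, reversed pairs, and self-loops).
random_edge_table <- function(n_rows, labels) {
  data.frame(a = sample(labels, n_rows, replace = TRUE),
             b = sample(labels, n_rows, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Connected-ish random instance for diffusion oracle checks: an ER
# graph regenerated until no isolates remain, plus a random
# non-negative signal matrix.
random_diffusion_instance <- function(n, p, n_cols, n_seeds) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (min(igraph::degree(g)) > 0L) break
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  nodes <- sprintf("N%03d", seq_len(n))
  net <- ppi_network(data.frame(a = nodes[el[, 1L]], b = nodes[el[, 2L]]))
  X <- matrix(0, n, n_cols, dimnames = list(net$nodes, NULL))
  seeds <- sample.int(n, n_seeds)
  X[seeds, ] <- matrix(runif(n_seeds * n_cols, 0, 3), n_seeds)
  list(network = net, X = X)
}

# The planted-brain-module world used by the recovery and ablation
# checks: 300 genes, sparse background, a 25-gene module that is
# densely wired, co-localized, and High in brain columns only.
planted_world <- function(rng_seed = 7L) {
  synthetic_spec(n_nodes = 300L, p = 0.02, n_seed_genes = 25L,
                 planted_module = list(size = 25L, p_within = 0.6,
                                       brain_high = TRUE),
                 rng_seed = rng_seed)
}
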