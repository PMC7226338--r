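# Shared fixtures and tiny independent oracles, all built in code.

# Two disjoint triangles, unit weights: component partition has L = log2(3).
two_triangles_net <- function() {
  weighted_network(data.frame(
    from = c("a1", "a2", "a3", "b1", "b2", "b3"),
    to   = c("a2", "a3", "a1", "b2", "b3", "b1"),
    weight = 1))
}

single_edge_net <- function() {
  weighted_network(data.frame(from = "c1", to = "p1", weight = 0.7),
                   node_type = c(c1 = "chaperone", p1 = "client"))
}

# Complete bipartite 2 x 2, equal weights.
k22_net <- function() {
  build_network(matrix(0.5, 2, 2, dimnames = list(c("c1", "c2"), c("p1", "p2"))))
}

# Small random weighted bipartite network (<= 8 nodes after dropping).
random_small_net <- function(seed, nr = 3, nc = 5) {
  m <- withr::with_seed(seed, {
    w <- matrix(stats::runif(nr * nc), nr, nc,
                dimnames = list(paste0("c", seq_len(nr)), paste0("p", seq_len(nc))))
    w[w < 0.45] <- 0
    w
  })
  if (all(m == 0)) m[1, 1] <- 0.5
  build_network(m)
}

# All permutations of 1..n as a matrix (n! rows); oracle helper for exact
# permutation tests of the Spearman p-value.
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

# Exact two-sided permutation p-value for a Spearman coefficient at tiny n.
perm_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  r_obs <- stats::cor(rx, ry)
  perms <- all_perms(length(y))
  r_all <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
  mean(abs(r_all) >= abs(r_obs) - 1e-12)
}

# Wrap a single-cohort weight matrix as a filtered_correlation.
as_filtered <- function(w, cohort_id = "c1", alpha = 1e-6) {
  structure(list(cohort_id = cohort_id, w = w, alpha_corrected = alpha),
            class = "filtered_correlation")
}
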