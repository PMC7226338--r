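# Two-stage permutation null for modular structure: curveball shuffling of
# the binary incidence matrix (row and column sums fixed exactly), random
# redistribution of the observed weights over the shuffled one-cells, and
# repeated community detection to build the null ensemble of description
# lengths.

#' Curveball shuffle of a binary incidence matrix
#'
#' Repeats `n_trades` times: pick two distinct rows uniformly at random, find
#' the columns held by exactly one of the two, and swap a uniformly random
#' subset split of those exchangeable columns between them.  Every trade
#' preserves all row and column sums exactly; enough trades give an
#' approximately uniform draw from the set of matrices with the observed
#' margins.
#'
#' @param binary_matrix matrix with entries in `{0, 1}`.
#' @param n_trades number of row-pair trades.
#' @return A shuffled binary matrix with identical margins.
#' @export
curveball_shuffle <- function(binary_matrix, n_trades) {
  if (!all(binary_matrix %in% c(0, 1))) stopf("curveball input must be binary")
  m <- binary_matrix
  nr <- nrow(m)
  if (nr < 2) return(m)
  rows <- lapply(seq_len(nr), function(i) which(m[i, ] == 1))
  for (t in seq_len(n_trades)) {
    ab <- sample.int(nr, 2)
    a <- rows[[ab[1]]]; b <- rows[[ab[2]]]
    shared <- intersect(a, b)
    only_a <- setdiff(a, shared)
    only_b <- setdiff(b, shared)
    exch <- c(only_a, only_b)
    if (length(exch) < 2 || !length(only_a) || !length(only_b)) next
    exch <- exch[sample.int(length(exch))]
    rows[[ab[1]]] <- c(shared, exch[seq_along(only_a)])
    rows[[ab[2]]] <- c(shared, exch[-seq_along(only_a)])
  }
  out <- matrix(0, nr, ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nr)) out[i, rows[[i]]] <- 1
  out
}

#' Redistribute observed weights over the one-cells of a binary matrix
#'
#' A uniformly random bijection from the observed weight multiset onto the
#' matrix's one-cells; zero-cells stay zero.  The nonzero-value multiset of
#' the output equals the input multiset for any seed.
#'
#' @param binary_matrix matrix with entries in `{0, 1}`.
#' @param weights numeric vector of positive weights, one per one-cell.
#' @return Weighted matrix of the same shape.
#' @export
redistribute_weights <- function(binary_matrix, weights) {
  if (!all(binary_matrix %in% c(0, 1))) stopf("binary incidence matrix required")
  ones <- which(binary_matrix == 1)
  if (length(ones) != length(weights)) {
    stopf("weight count (%d) does not match one-cell count (%d)",
          length(weights), length(ones))
  }
  out <- matrix(0, nrow(binary_matrix), ncol(binary_matrix),
                dimnames = dimnames(binary_matrix))
  out[ones] <- if (length(weights) > 1) sample(weights) else weights
  out
}

# Reconstruct the chaperone x client weight matrix underlying a bipartite
# chapnet (dropped zero-degree genes are irrelevant to the null, which
# preserves margins >= 1).
incidence_from_network <- function(net) {
  chap <- net$nodes$node[net$nodes$type == "chaperone"]
  clnt <- net$nodes$node[net$nodes$type == "client"]
  if (!length(chap) || !length(clnt)) {
    stopf("null test requires a bipartite chaperone/client network")
  }
  w <- matrix(0, length(chap), length(clnt), dimnames = list(chap, clnt))
  swap <- !(net$edges$from %in% chap)
  from <- ifelse(swap, net$edges$to, net$edges$from)
  to <- ifelse(swap, net$edges$from, net$edges$to)
  w[cbind(match(from, chap), match(to, clnt))] <- net$edges$weight
  w
}

#' Permutation test for non-random modular structure
#'
#' Computes `L_obs` by community detection on the observed network, then for
#' each of `n_sim` replicates shuffles the binary incidence matrix with the
#' curveball algorithm (`n_trades = n_trades_factor` times the number of
#' chaperone rows), redistributes the observed weights over the shuffled
#' one-cells, and re-optimises the partition to obtain `L_sim`.  The
#' one-tailed p-value is, under the default direction
#' `"random_at_least_as_good"`, the fraction of replicates whose partition
#' describes the walk at least as compactly as the observed one
#' (`L_sim <= L_obs`); `"as_printed"` instead counts `L_sim > L_obs`.
#'
#' @param net a bipartite `chapnet`.
#' @param n_sim number of randomised replicates (>= 1).
#' @param n_restarts restarts for every [detect_communities()] call, observed
#'   and simulated alike (equal search effort avoids bias in the comparison).
#' @param seed integer master seed; replicate streams are derived from
#'   `(seed, replicate index)` so results are independent of execution order.
#' @param direction `"random_at_least_as_good"` (default) or `"as_printed"`.
#' @param n_trades_factor trades per chaperone row (default 5, the original
#'   curveball recommendation).
#' @param check_conservation verify margins and weight multisets on every
#'   replicate (cheap; on by default).
#' @return A `null_test_result`: list with `L_obs`, `L_sims`, `n_sim`,
#'   `n_trades`, `p_value`, `direction`, `seed`, and `partition`/`score` of
#'   the observed fit.
#' @export
null_ensemble_test <- function(net, n_sim = 1000, n_restarts = 10, seed = 1,
                               direction = c("random_at_least_as_good", "as_printed"),
                               n_trades_factor = 5,
                               check_conservation = TRUE) {
  direction <- match.arg(direction)
  if (!is_count(n_sim)) stopf("`n_sim` must be a positive integer")
  n_sim <- as.integer(n_sim)
  w_obs <- incidence_from_network(net)
  binary <- (w_obs > 0) * 1
  weights <- w_obs[w_obs > 0]
  n_trades <- n_trades_factor * nrow(binary)

  obs <- detect_communities(net, n_restarts = n_restarts, seed = seed)
  L_obs <- obs$score$L

  rep_seeds <- derive_seeds(seed, n_sim)
  types <- stats::setNames(
    c(rep("chaperone", nrow(binary)), rep("client", ncol(binary))),
    c(rownames(binary), colnames(binary)))
  L_sims <- vapply(seq_len(n_sim), function(i) {
    sim <- with_seed(rep_seeds[i], {
      b <- curveball_shuffle(binary, n_trades)
      redistribute_weights(b, weights)
    })
    if (check_conservation) {
      stopifnot(identical(rowSums(sim > 0), rowSums(binary == 1)),
                identical(colSums(sim > 0), colSums(binary == 1)),
                isTRUE(all.equal(sort(sim[sim > 0]), sort(weights))))
    }
    pos <- which(sim > 0, arr.ind = TRUE)
    edges <- data.frame(from = rownames(sim)[pos[, 1]],
                        to = colnames(sim)[pos[, 2]],
                        weight = sim[pos], stringsAsFactors = FALSE)
    sim_net <- weighted_network(edges, node_type = types)
    detect_communities(sim_net, n_restarts = n_restarts,
                       seed = rep_seeds[i])$score$L
  }, 0)

  count <- if (direction == "random_at_least_as_good") {
    sum(L_sims <= L_obs)
  } else {
    sum(L_sims > L_obs)
  }
  structure(list(L_obs = L_obs, L_sims = L_sims, n_sim = n_sim,
                 n_trades = n_trades, p_value = count / n_sim,
                 direction = direction, seed = seed,
                 partition = obs$partition, score = obs$score),
            class = "null_test_result")
}

#' @export
print.null_test_result <- function(x, ...) {
  cat(sprintf("Map-equation permutation null (%d replicates, %d trades)\n",
              x$n_sim, x$n_trades))
  cat(sprintf("  L_obs = %.6f bits; null L range [%.6f, %.6f]\n",
              x$L_obs, min(x$L_sims), max(x$L_sims)))
  p_txt <- if (x$p_value == 0) sprintf("< %g", 1 / x$n_sim) else sprintf("= %g", x$p_value)
  cat(sprintf("  one-tailed p %s (direction: %s)\n", p_txt, x$direction))
  invisible(x)
}

#' Write a null-test result as JSON (and optionally the L ensemble as TSV)
#' @param res a `null_test_result`.
#' @param path output JSON path.
#' @param path_sims optional TSV of the simulated L values.
#' @return Invisibly `path`.
#' @export
write_nulltest_json <- function(res, path, path_sims = NULL) {
  jsonlite::write_json(
    list(L_obs = res$L_obs, L_sims = res$L_sims, n_sim = res$n_sim,
         n_trades = res$n_trades, direction = res$direction,
         p_value = res$p_value, seed = res$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path_sims)) {
    utils::write.table(data.frame(replicate = seq_along(res$L_sims),
                                  L = fmt_num(res$L_sims)),
                       path_sims, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
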