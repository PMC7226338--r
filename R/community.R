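# Weighted bipartite network construction and two-level map-equation
# community detection.  The bipartite graph is treated as an undirected
# weighted unipartite graph for flow purposes: a random walker follows edge
# weights, and a partition is scored by the per-step description length L of
# the walk under a two-level modular code.  The greedy search lives in
# src/map_equation.cpp; an exhaustive enumeration oracle is provided for
# small graphs.

#' Build a weighted network from an edge table
#'
#' General constructor used by the tests and by [build_network()].  Node
#' `type` defaults to `"node"`; the bipartite builder tags chaperones and
#' clients.
#'
#' @param edges data.frame with columns `from`, `to`, `weight` (> 0).
#' @param node_type optional named character vector of node types.
#' @param dropped_nodes zero-degree genes excluded from the network.
#' @return A `chapnet` object: `nodes` (data.frame `node`, `type`), `edges`,
#'   `dropped_nodes`.
#' @export
weighted_network <- function(edges, node_type = NULL, dropped_nodes = character()) {
  stopifnot(is.data.frame(edges), all(c("from", "to", "weight") %in% names(edges)))
  if (!nrow(edges)) stopf("empty network")
  if (any(edges$weight <= 0)) stopf("edge weights must be strictly positive")
  if (any(edges$from == edges$to)) stopf("self-loops are not allowed")
  nodes <- unique(c(edges$from, edges$to))
  type <- if (is.null(node_type)) {
    stats::setNames(rep("node", length(nodes)), nodes)
  } else {
    node_type[nodes]
  }
  structure(list(
    nodes = data.frame(node = nodes, type = unname(type),
                       stringsAsFactors = FALSE),
    edges = data.frame(from = as.character(edges$from),
                       to = as.character(edges$to),
                       weight = as.numeric(edges$weight),
                       stringsAsFactors = FALSE),
    dropped_nodes = dropped_nodes),
    class = "chapnet")
}

#' Build the weighted bipartite chaperone-client network
#'
#' One undirected weighted edge per strictly positive cell of the pan-cancer
#' matrix.  Genes with no positive cell (the unassociated proteins) are
#' recorded in `dropped_nodes` rather than carried as isolated vertices.
#'
#' @param pc a `pancancer_matrix` or plain chaperone x client weight matrix.
#' @return A `chapnet` with node types `"chaperone"` / `"client"`.
#' @export
build_network <- function(pc) {
  w <- if (inherits(pc, "pancancer_matrix")) pc$w_med else pc
  stopifnot(is.matrix(w), !is.null(rownames(w)), !is.null(colnames(w)))
  pos <- which(w > 0, arr.ind = TRUE)
  if (!nrow(pos)) stopf("empty network: no strictly positive cell")
  edges <- data.frame(from = rownames(w)[pos[, 1]],
                      to = colnames(w)[pos[, 2]],
                      weight = w[pos],
                      stringsAsFactors = FALSE)
  dropped <- c(rownames(w)[rowSums(w > 0) == 0],
               colnames(w)[colSums(w > 0) == 0])
  types <- stats::setNames(
    c(rep("chaperone", nrow(w)), rep("client", ncol(w))),
    c(rownames(w), colnames(w)))
  weighted_network(edges, node_type = types, dropped_nodes = dropped)
}

# Internal indexed representation used by the scoring/search routines.
net_index <- function(net) {
  nodes <- net$nodes$node
  from <- match(net$edges$from, nodes)
  to <- match(net$edges$to, nodes)
  strength <- numeric(length(nodes))
  for (e in seq_along(from)) {
    strength[from[e]] <- strength[from[e]] + net$edges$weight[e]
    strength[to[e]] <- strength[to[e]] + net$edges$weight[e]
  }
  list(nodes = nodes, n = length(nodes), from = from, to = to,
       w = net$edges$weight, strength = strength,
       W = sum(net$edges$weight))
}

as_assignment <- function(part, nodes) {
  a <- if (inherits(part, "partition")) part$assignment else part
  if (is.null(names(a))) stopf("partition must be a named vector")
  missing <- setdiff(nodes, names(a))
  if (length(missing)) {
    stopf("node(s) missing from partition: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  as.integer(as.factor(a[nodes]))
}

new_partition <- function(assignment, nodes) {
  lab <- integer(length(nodes))
  seen <- integer(0)
  nxt <- 1L
  for (i in seq_along(assignment)) {   # contiguous labels by first appearance
    m <- assignment[i]
    pos <- match(m, seen)
    if (is.na(pos)) {
      seen <- c(seen, m)
      pos <- nxt
      nxt <- nxt + 1L
    }
    lab[i] <- pos
  }
  structure(list(assignment = stats::setNames(lab, nodes),
                 n_modules = max(lab)),
            class = "partition")
}

#' Two-level map equation of a partition
#'
#' Scores a partition of the network by the average per-step description
#' length (bits) of a random walk under a two-level code.  Node visit rates
#' are `p_a = strength(a) / 2W`; module exit rates are
#' `q_i = (cut weight of module i) / 2W`; and
#' `L = q H(Q) + sum_i p_i_circ H(P_i)` with `q = sum q_i`,
#' `p_i_circ = q_i + sum_{a in i} p_a`, entropies base 2, and `0 log 0 = 0`.
#'
#' @param net a `chapnet`.
#' @param part a `partition` or named module vector covering every node.
#' @return A `partition_score`: list with `L` (bits) and `per_module`
#'   data.frame (`module`, `visit_rate`, `exit_rate`).
#' @export
map_equation <- function(net, part) {
  g <- net_index(net)
  m <- as_assignment(part, g$nodes)
  W2 <- 2 * g$W
  p <- g$strength / W2
  nmod <- max(m)
  P <- vapply(seq_len(nmod), function(i) sum(p[m == i]), 0)
  cut <- numeric(nmod)
  between <- m[g$from] != m[g$to]
  if (any(between)) {
    for (e in which(between)) {
      cut[m[g$from[e]]] <- cut[m[g$from[e]]] + g$w[e]
      cut[m[g$to[e]]] <- cut[m[g$to[e]]] + g$w[e]
    }
  }
  q <- cut / W2
  L <- sum(plogp(sum(q))) - 2 * sum(plogp(q)) + sum(plogp(q + P)) - sum(plogp(p))
  structure(list(L = L,
                 per_module = data.frame(module = seq_len(nmod),
                                         visit_rate = P,
                                         exit_rate = q)),
            class = "partition_score")
}

#' Detect communities by minimising the map equation
#'
#' Seeded greedy search: each restart sweeps nodes in random order, moving a
#' node to the neighbouring module that most decreases L (starting from
#' singletons), iterating to convergence, then attempts module merges, and
#' alternates until a full pass improves L by less than `tol` bits.  The best
#' of `n_restarts` runs is additionally compared against the single-module
#' and all-singletons partitions, so the returned L never exceeds either
#' baseline.  Deterministic given `seed`.
#'
#' @param net a `chapnet`.
#' @param n_restarts number of random-order restarts (>= 1).
#' @param seed integer seed.
#' @param tol convergence threshold in bits.
#' @return List with `partition` and `score`.
#' @export
detect_communities <- function(net, n_restarts = 10, seed = 1, tol = 1e-10) {
  if (!is_count(n_restarts)) stopf("`n_restarts` must be a positive integer")
  g <- net_index(net)
  if (!g$n) stopf("empty network")
  orders <- with_seed(seed, {
    t(vapply(seq_len(n_restarts), function(i) sample.int(g$n), integer(g$n)))
  })
  res <- cpp_greedy(g$n, g$from, g$to, g$w, orders, tol)
  part <- new_partition(res$assignment, g$nodes)

  # explicit baseline candidates
  one <- new_partition(rep(1L, g$n), g$nodes)
  singles <- new_partition(seq_len(g$n), g$nodes)
  cands <- list(part, one, singles)
  Ls <- vapply(cands, function(p) map_equation(net, p)$L, 0)
  best <- which.min(Ls)
  part <- cands[[best]]
  list(partition = part, score = map_equation(net, part))
}

#' Exhaustive minimum-L partition (small-graph oracle)
#'
#' Enumerates every set partition of the nodes (restricted-growth-string
#' enumeration, Bell-number many) and returns the global minimum of the map
#' equation.  Ties are broken by fewer modules, then by lexicographically
#' smallest assignment.  Intended as an independent oracle for graphs of at
#' most `max_nodes` nodes.
#'
#' @param net a `chapnet`.
#' @param max_nodes refuse larger graphs (default 10; B(10) = 115975).
#' @return List with `partition` and `score`.
#' @export
exhaustive_partition_search <- function(net, max_nodes = 10) {
  g <- net_index(net)
  if (g$n > max_nodes) stopf("network has %d nodes, oracle limit is %d", g$n, max_nodes)
  best <- list(L = Inf, assignment = NULL, k = Inf)
  assignment <- integer(g$n)
  W2 <- 2 * g$W
  p <- g$strength / W2

  score <- function(m) {
    nmod <- max(m)
    P <- vapply(seq_len(nmod), function(i) sum(p[m == i]), 0)
    cut <- numeric(nmod)
    between <- m[g$from] != m[g$to]
    for (e in which(between)) {
      cut[m[g$from[e]]] <- cut[m[g$from[e]]] + g$w[e]
      cut[m[g$to[e]]] <- cut[m[g$to[e]]] + g$w[e]
    }
    q <- cut / W2
    sum(plogp(sum(q))) - 2 * sum(plogp(q)) + sum(plogp(q + P)) - sum(plogp(p))
  }

  recurse <- function(i, kmax) {
    if (i > g$n) {
      L <- score(assignment[seq_len(g$n)])
      k <- max(assignment)
      better <- L < best$L - 1e-15 ||
        (abs(L - best$L) <= 1e-15 &&
           (k < best$k ||
              (k == best$k &&
                 !is.null(best$assignment) &&
                 paste(assignment, collapse = ",") <
                   paste(best$assignment, collapse = ","))))
      if (better || is.null(best$assignment)) {
        if (better) best <<- list(L = L, assignment = assignment, k = k)
      }
      return(invisible())
    }
    for (lab in seq_len(kmax + 1L)) {
      assignment[i] <<- lab
      recurse(i + 1L, max(kmax, lab))
    }
  }
  assignment[1] <- 1L
  recurse(2L, 1L)
  if (g$n == 1L) best <- list(L = score(1L), assignment = 1L, k = 1L)
  part <- new_partition(best$assignment, g$nodes)
  list(partition = part, score = map_equation(net, part))
}

#' Name modules after their highest-degree chaperone
#'
#' Observed modules are conventionally labelled by the chaperone with the
#' most interactions inside them; modules without a chaperone keep their
#' numeric label.
#'
#' @param net a `chapnet` with `"chaperone"` node types.
#' @param part a `partition`.
#' @return named character vector: module label -> name.
#' @export
name_modules <- function(net, part) {
  deg <- table(c(net$edges$from, net$edges$to))
  chap <- net$nodes$node[net$nodes$type == "chaperone"]
  a <- part$assignment
  out <- character(part$n_modules)
  for (i in seq_len(part$n_modules)) {
    members <- intersect(names(a)[a == i], chap)
    out[i] <- if (length(members)) {
      members[which.max(deg[members])]
    } else {
      as.character(i)
    }
  }
  stats::setNames(out, as.character(seq_len(part$n_modules)))
}

#' Adjusted Rand index between two labelings
#'
#' Standard contingency-table formula; used as an independent check of
#' planted-structure recovery.
#'
#' @param a,b named label vectors over the same items (order-insensitive).
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  }
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}

#' Export a network for Cytoscape-style tools
#'
#' Weighted edge-list TSV (`source`, `target`, `weight`) plus a node
#' attribute TSV (`node`, `type`, `module`, `degree`).
#'
#' @param net a `chapnet`.
#' @param part optional `partition` supplying module labels.
#' @param path_edges,path_nodes output TSV paths (`NULL` to skip).
#' @return Invisibly `net`.
#' @export
write_network_tsv <- function(net, part = NULL, path_edges = NULL, path_nodes = NULL) {
  if (!is.null(path_edges)) {
    out <- data.frame(source = net$edges$from, target = net$edges$to,
                      weight = fmt_num(net$edges$weight),
                      stringsAsFactors = FALSE)
    utils::write.table(out, path_edges, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(path_nodes)) {
    deg <- table(c(net$edges$from, net$edges$to))
    nd <- net$nodes
    nd$module <- if (!is.null(part)) unname(part$assignment[nd$node]) else NA_integer_
    nd$degree <- as.integer(deg[nd$node])
    utils::write.table(nd, path_nodes, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(net)
}

#' Write a partition and its score as JSON
#' @param part a `partition`.
#' @param score a `partition_score`.
#' @param path output JSON path.
#' @param module_names optional named module labels.
#' @return Invisibly `path`.
#' @export
write_partition_json <- function(part, score, path, module_names = NULL) {
  jsonlite::write_json(
    list(assignment = as.list(part$assignment),
         n_modules = part$n_modules,
         L = score$L,
         per_module = score$per_module,
         module_names = as.list(module_names %||% character())),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
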