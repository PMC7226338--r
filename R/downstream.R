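# Downstream summaries of the pan-cancer matrix: hierarchical clustering of
# interaction profiles and pairwise client-set partitions.

#' Hierarchically cluster interaction profiles
#'
#' For `axis = "chaperone_by_chaperone"` the input is a chaperone x chaperone
#' pan-cancer weight matrix and the pairwise distance is `1 - w`; for
#' `axis = "chaperone_by_client"` chaperones are clustered by the Pearson
#' correlation of their client-interaction rows, distance `1 - r`.  A
#' constant profile (zero variance) has undefined correlation; its distance
#' to every other item is set to 1 and the item is flagged.  Agglomeration
#' uses the chosen linkage (average by default).
#'
#' @param matrix pan-cancer weight matrix (or `pancancer_matrix`).
#' @param axis which profile geometry to cluster.
#' @param linkage `"average"` (default), `"single"`, or `"complete"`.
#' @return A `profile_dendrogram`: list with `hclust`, `distance` (dist),
#'   `flagged` (constant items), `axis`, `linkage`.
#' @export
cluster_profiles <- function(matrix,
                             axis = c("chaperone_by_chaperone", "chaperone_by_client"),
                             linkage = c("average", "single", "complete")) {
  axis <- match.arg(axis)
  linkage <- match.arg(linkage)
  w <- if (inherits(matrix, "pancancer_matrix")) matrix$w_med else matrix
  stopifnot(is.matrix(w), !is.null(rownames(w)))
  if (nrow(w) < 2) stopf("need >= 2 items to cluster")
  items <- rownames(w)
  flagged <- character()
  if (axis == "chaperone_by_chaperone") {
    if (nrow(w) != ncol(w)) stopf("chaperone_by_chaperone needs a square matrix")
    d <- 1 - w
    d <- (d + t(d)) / 2      # symmetrise against asymmetric input
    diag(d) <- 0
  } else {
    sds <- apply(w, 1, stats::sd)
    flagged <- items[sds == 0]
    r <- suppressWarnings(stats::cor(t(w)))
    r[is.na(r)] <- 0
    d <- 1 - r
    if (length(flagged)) {
      d[flagged, ] <- 1
      d[, flagged] <- 1
    }
    diag(d) <- 0
  }
  # deterministic order: hclust with items pre-sorted by label as tie-break
  ord <- order(items)
  d <- d[ord, ord]
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  structure(list(hclust = hc, distance = stats::as.dist(d),
                 flagged = flagged, axis = axis, linkage = linkage),
            class = "profile_dendrogram")
}

#' Serialise a dendrogram as Newick and as a merge-table TSV
#'
#' Branch lengths are merge heights in `1 - r` distance units.
#'
#' @param dend a `profile_dendrogram`.
#' @param path_newick,path_merges output paths (`NULL` to skip either).
#' @return Invisibly the `ape::phylo` tree.
#' @export
write_dendrogram <- function(dend, path_newick = NULL, path_merges = NULL) {
  stopifnot(inherits(dend, "profile_dendrogram"))
  tree <- ape::as.phylo(dend$hclust)
  if (!is.null(path_newick)) ape::write.tree(tree, file = path_newick)
  if (!is.null(path_merges)) {
    hc <- dend$hclust
    utils::write.table(
      data.frame(step = seq_len(nrow(hc$merge)),
                 left = hc$merge[, 1], right = hc$merge[, 2],
                 height = fmt_num(hc$height)),
      path_merges, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(tree)
}

#' Partition the client panel by co-expression with two chaperones
#'
#' A client is "co-expressed with" a chaperone when its pan-cancer weight is
#' strictly positive (the same rule that defines network edges).  The client
#' panel splits into four disjoint sets: co-expressed with both chaperones,
#' with only one, or with neither.
#'
#' @param pc a `pancancer_matrix` (or chaperone x client matrix).
#' @param chap_a,chap_b chaperone row names.
#' @return A `client_set_partition`: list with the four gene sets, their
#'   counts, and the chaperone ids.
#' @export
client_set_partition <- function(pc, chap_a, chap_b) {
  w <- if (inherits(pc, "pancancer_matrix")) pc$w_med else pc
  for (ch in c(chap_a, chap_b)) {
    if (!ch %in% rownames(w)) stopf("unknown chaperone '%s'", ch)
  }
  clients <- setdiff(colnames(w), c(chap_a, chap_b))  # exclude self-pairs
  in_a <- w[chap_a, clients] > 0
  in_b <- w[chap_b, clients] > 0
  sets <- list(both = clients[in_a & in_b],
               only_a = clients[in_a & !in_b],
               only_b = clients[!in_a & in_b],
               neither = clients[!in_a & !in_b])
  structure(c(list(chap_a = chap_a, chap_b = chap_b), sets,
              list(counts = vapply(sets, length, 0L))),
            class = "client_set_partition")
}

#' Write a client-set partition as JSON and a 4-row summary TSV
#' @param csp a `client_set_partition`.
#' @param path_json,path_tsv output paths (`NULL` to skip either).
#' @return Invisibly `csp`.
#' @export
write_client_sets <- function(csp, path_json = NULL, path_tsv = NULL) {
  stopifnot(inherits(csp, "client_set_partition"))
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(chap_a = csp$chap_a, chap_b = csp$chap_b,
           both = csp$both, only_a = csp$only_a,
           only_b = csp$only_b, neither = csp$neither,
           counts = as.list(csp$counts)),
      path_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(path_tsv)) {
    utils::write.table(
      data.frame(set = names(csp$counts), count = unname(csp$counts)),
      path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(csp)
}
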