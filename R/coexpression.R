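# Per-cohort Spearman screening between a chaperone panel and a client panel,
# with Bonferroni-corrected significance zeroing and a positivity filter.

#' Spearman correlation between two gene panels
#'
#' Computes the chaperone x client matrix of Spearman coefficients (Pearson
#' correlation of average-ranked values) and two-sided p-values from the
#' large-sample t approximation with `n - 2` degrees of freedom.  Genes with
#' zero rank variance (constant across samples) are recorded with `r = 0`,
#' `p = 1` and flagged; a gene present in both panels yields a self-pair with
#' `r = 1`, `p = 0`, flagged for downstream exclusion.
#'
#' @param expr genes x samples non-negative matrix with gene row names.
#' @param chaperones,clients character vectors of gene ids; all must be rows
#'   of `expr` unless `missing_ok = TRUE`, in which case absent genes are
#'   dropped with a warning.
#' @param cohort_id label carried into the result.
#' @param missing_ok permissive flag for absent panel genes.
#' @return A `correlation_result`: list with `cohort_id`, `r`, `p`,
#'   `n_samples`, `constant_genes`, and `self_pairs` (logical matrix).
#' @export
spearman_panel <- function(expr, chaperones, clients,
                           cohort_id = "cohort", missing_ok = FALSE) {
  validate_expression(expr)
  if (ncol(expr) < 3) stopf("need >= 3 samples to compute correlations (got %d)", ncol(expr))

  check_panel <- function(panel, what) {
    missing <- setdiff(panel, rownames(expr))
    if (length(missing)) {
      if (!missing_ok) {
        stopf("%s panel gene(s) missing from expression matrix: %s",
              what, paste(utils::head(missing, 5), collapse = ", "))
      }
      warning(sprintf("dropping %d missing %s panel gene(s): %s",
                      length(missing), what,
                      paste(utils::head(missing, 5), collapse = ", ")),
              call. = FALSE)
      panel <- setdiff(panel, missing)
    }
    panel
  }
  chaperones <- check_panel(chaperones, "chaperone")
  clients <- check_panel(clients, "client")
  if (!length(chaperones) || !length(clients)) stopf("empty panel after dropping missing genes")

  n <- ncol(expr)
  genes <- union(chaperones, clients)
  ranks <- t(apply(expr[genes, , drop = FALSE], 1, rank))  # average ranks for ties
  rownames(ranks) <- genes

  sds <- apply(ranks, 1, stats::sd)
  constant <- names(sds)[sds == 0]
  # A constant gene has undefined rank correlation; record r = 0, p = 1.
  ok <- setdiff(genes, constant)

  r <- matrix(0, length(chaperones), length(clients),
              dimnames = list(chaperones, clients))
  p <- matrix(1, length(chaperones), length(clients),
              dimnames = list(chaperones, clients))
  chap_ok <- intersect(chaperones, ok)
  clnt_ok <- intersect(clients, ok)
  if (length(chap_ok) && length(clnt_ok)) {
    r_ok <- stats::cor(t(ranks[chap_ok, , drop = FALSE]),
                       t(ranks[clnt_ok, , drop = FALSE]))
    r_ok <- pmin(pmax(r_ok, -1), 1)
    tstat <- r_ok * sqrt((n - 2) / pmax(1 - r_ok^2, .Machine$double.eps))
    p_ok <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p_ok[abs(r_ok) == 1] <- 0
    r[chap_ok, clnt_ok] <- r_ok
    p[chap_ok, clnt_ok] <- p_ok
  }

  self <- outer(chaperones, clients, `==`)
  dimnames(self) <- dimnames(r)
  r[self] <- 1
  p[self] <- 0

  structure(list(cohort_id = cohort_id, r = r, p = p, n_samples = n,
                 constant_genes = constant, self_pairs = self),
            class = "correlation_result")
}

#' Bonferroni-corrected significance threshold
#'
#' The per-test threshold `alpha / (n_chaperones * n_clients)`.  With the
#' study panels of 15 chaperones and 1142 clients this gives
#' `0.05 / 17130 = 2.9e-6` (two significant digits).  The family is
#' per-cohort, not pooled across cohorts.
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param n_chaperones,n_clients panel sizes (>= 1).
#' @return corrected per-test alpha.
#' @export
bonferroni_alpha <- function(alpha, n_chaperones, n_clients) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1)) {
    stopf("`alpha` must lie in (0, 1)")
  }
  if (!is_count(n_chaperones) || !is_count(n_clients)) {
    stopf("panel sizes must be positive integers")
  }
  alpha / (n_chaperones * n_clients)
}

#' Zero non-significant and negative correlations
#'
#' A pair keeps its coefficient as an interaction weight only if
#' `p < alpha_corrected` and `r > 0`; every other cell (including flagged
#' self-pairs, which are uninformative) becomes 0.
#'
#' @param res a `correlation_result`.
#' @param alpha_corrected per-test threshold, typically from
#'   [bonferroni_alpha()].
#' @return A `filtered_correlation`: list with `cohort_id`, `w` (weights in
#'   `[0, 1]`), and `alpha_corrected`.
#' @export
filter_correlations <- function(res, alpha_corrected) {
  stopifnot(inherits(res, "correlation_result"))
  if (!(is.numeric(alpha_corrected) && length(alpha_corrected) == 1L &&
        alpha_corrected > 0 && alpha_corrected < 1)) {
    stopf("`alpha_corrected` must lie in (0, 1)")
  }
  if (!identical(dim(res$r), dim(res$p))) stopf("r/p shape mismatch")
  keep <- res$p < alpha_corrected & res$r > 0 & !res$self_pairs
  w <- ifelse(keep, res$r, 0)
  dimnames(w) <- dimnames(res$r)
  structure(list(cohort_id = res$cohort_id, w = w,
                 alpha_corrected = alpha_corrected),
            class = "filtered_correlation")
}

#' Write a correlation result in long and wide form
#'
#' @param res a `correlation_result`.
#' @param filtered the matching `filtered_correlation` (supplies `w`).
#' @param path_long,path_wide output TSV paths (`NULL` to skip either).
#' @return Invisibly, the long-format data.frame.
#' @export
write_correlations_tsv <- function(res, filtered, path_long = NULL, path_wide = NULL) {
  long <- data.frame(
    cohort = res$cohort_id,
    chaperone = rep(rownames(res$r), times = ncol(res$r)),
    client = rep(colnames(res$r), each = nrow(res$r)),
    r = as.vector(res$r),
    p = as.vector(res$p),
    w = as.vector(filtered$w),
    stringsAsFactors = FALSE)
  if (!is.null(path_long)) {
    out <- long
    out$r <- fmt_num(out$r); out$p <- fmt_num(out$p); out$w <- fmt_num(out$w)
    utils::write.table(out, path_long, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(path_wide)) write_matrix_tsv(filtered$w, path_wide, row_label = "chaperone")
  invisible(long)
}
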