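# Pan-cancer aggregation: cell-wise median of per-cohort filtered matrices
# (zeros from non-significant cohorts included) and degree summaries.

#' Aggregate filtered correlation matrices by the cell-wise median
#'
#' Every cell's pan-cancer weight is the median of its per-cohort filtered
#' weights, zeros included.  With an odd cohort count this is the middle order
#' statistic, so a pair only keeps a positive weight when it is significantly
#' positively correlated in a strict majority of cohorts; with an even count
#' the mean of the two middle values is used.
#'
#' @param filtered non-empty list of `filtered_correlation` objects sharing
#'   identical chaperone and client orderings.
#' @return A `pancancer_matrix`: list with `w_med` (chaperone x client),
#'   `n_cohorts`, `cohort_ids`.
#' @export
aggregate_median <- function(filtered) {
  if (!length(filtered)) stopf("need at least one filtered matrix")
  lapply(filtered, function(f) stopifnot(inherits(f, "filtered_correlation")))
  ref <- filtered[[1]]$w
  for (f in filtered[-1]) {
    if (!identical(dim(f$w), dim(ref))) {
      stopf("matrix shape mismatch between cohorts %s and %s",
            filtered[[1]]$cohort_id, f$cohort_id)
    }
    mism <- which(rownames(f$w) != rownames(ref))
    if (length(mism)) {
      stopf("chaperone ordering mismatch at '%s' (cohort %s)",
            rownames(f$w)[mism[1]], f$cohort_id)
    }
    mism <- which(colnames(f$w) != colnames(ref))
    if (length(mism)) {
      stopf("client ordering mismatch at '%s' (cohort %s)",
            colnames(f$w)[mism[1]], f$cohort_id)
    }
  }
  arr <- vapply(filtered, function(f) f$w, ref)       # rows x cols x cohorts
  w_med <- apply(arr, c(1, 2), stats::median)
  dimnames(w_med) <- dimnames(ref)
  structure(list(w_med = w_med,
                 n_cohorts = length(filtered),
                 cohort_ids = vapply(filtered, `[[`, "", "cohort_id")),
            class = "pancancer_matrix")
}

#' Degree summary of a pan-cancer matrix
#'
#' Counts strictly positive cells per chaperone and per client, the median
#' chaperone count over clients with at least one interaction, the number of
#' interacting clients, and the total interaction count.
#'
#' @param pc a `pancancer_matrix` (or plain weight matrix).
#' @return A `degree_summary` list.
#' @export
degree_summary <- function(pc) {
  w <- if (inherits(pc, "pancancer_matrix")) pc$w_med else pc
  pos <- w > 0
  per_client <- colSums(pos)
  per_chap <- rowSums(pos)
  interacting <- per_client >= 1
  structure(list(
    per_client_chaperone_count = per_client,
    per_chaperone_client_count = per_chap,
    median_chaperones_per_client = if (any(interacting)) {
      stats::median(per_client[interacting])
    } else NA_real_,
    n_interacting_proteins = sum(interacting),
    n_interactions = sum(pos)
  ), class = "degree_summary")
}

#' Write pan-cancer artifacts
#'
#' Wide and long TSV for the matrix; JSON for the degree summary.
#'
#' @param pc a `pancancer_matrix`.
#' @param path_wide,path_long,path_summary output paths (`NULL` to skip).
#' @return Invisibly `pc`.
#' @export
write_pancancer <- function(pc, path_wide = NULL, path_long = NULL,
                            path_summary = NULL) {
  stopifnot(inherits(pc, "pancancer_matrix"))
  if (!is.null(path_wide)) write_matrix_tsv(pc$w_med, path_wide, "chaperone")
  if (!is.null(path_long)) {
    long <- data.frame(
      chaperone = rep(rownames(pc$w_med), times = ncol(pc$w_med)),
      client = rep(colnames(pc$w_med), each = nrow(pc$w_med)),
      w_med = fmt_num(as.vector(pc$w_med)),
      stringsAsFactors = FALSE)
    utils::write.table(long, path_long, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(path_summary)) {
    ds <- degree_summary(pc)
    jsonlite::write_json(
      list(per_client_chaperone_count = as.list(ds$per_client_chaperone_count),
           per_chaperone_client_count = as.list(ds$per_chaperone_client_count),
           median_chaperones_per_client = ds$median_chaperones_per_client,
           n_interacting_proteins = ds$n_interacting_proteins,
           n_interactions = ds$n_interactions),
      path_summary, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(pc)
}
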