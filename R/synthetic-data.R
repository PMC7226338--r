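#' Configuration for the synthetic multi-cohort generator
#'
#' Describes a simulated pan-cancer study: `n_cohorts` tumour cohorts, each
#' with `n_samples_per_cohort` samples, profiled over a chaperone panel and a
#' client panel whose members load on `n_modules` latent module factors.
#' Expression is generated in log-space (Gaussian factors plus noise) and
#' exponentiated, so values are positive and FPKM-like; rank-based statistics
#' downstream only see the monotone structure.
#'
#' @param n_cohorts number of cohorts (the real study used 13 tumour entities).
#' @param n_samples_per_cohort samples per cohort.
#' @param n_chaperones,n_clients panel sizes.
#' @param n_modules number K of planted modules; must not exceed either panel.
#' @param within_module_loading loading of a gene on its own module factor,
#'   in `[0, 1]`; must exceed `cross_module_loading` so planted structure is
#'   detectable by construction.
#' @param cross_module_loading loading on the mean of the other factors.
#' @param frac_unassigned_clients fraction of clients that are noise-only
#'   (no module membership), in `[0, 1]`.
#' @param noise_sd standard deviation of the log-space Gaussian noise (> 0).
#' @param seed integer seed; the bundle is deterministic given the config.
#'
#' @return An object of class `synthetic_config`.
#' @seealso [generate_cohort_bundle()]
#' @export
synthetic_config <- function(n_cohorts = 13,
                             n_samples_per_cohort = 200,
                             n_chaperones = 15,
                             n_clients = 90,
                             n_modules = 3,
                             within_module_loading = 0.9,
                             cross_module_loading = 0.05,
                             frac_unassigned_clients = 0.15,
                             noise_sd = 0.3,
                             seed = 1) {
  cfg <- list(
    n_cohorts = n_cohorts,
    n_samples_per_cohort = n_samples_per_cohort,
    n_chaperones = n_chaperones,
    n_clients = n_clients,
    n_modules = n_modules,
    within_module_loading = within_module_loading,
    cross_module_loading = cross_module_loading,
    frac_unassigned_clients = frac_unassigned_clients,
    noise_sd = noise_sd,
    seed = seed
  )
  for (f in c("n_cohorts", "n_samples_per_cohort", "n_chaperones",
              "n_clients", "n_modules")) {
    if (!is_count(cfg[[f]])) stopf("configuration error: `%s` must be a positive integer", f)
  }
  for (f in c("within_module_loading", "cross_module_loading",
              "frac_unassigned_clients")) {
    if (!is_prob(cfg[[f]])) stopf("configuration error: `%s` must lie in [0, 1]", f)
  }
  if (!(is.numeric(noise_sd) && length(noise_sd) == 1L && noise_sd > 0)) {
    stopf("configuration error: `noise_sd` must be > 0")
  }
  if (!(within_module_loading > cross_module_loading ||
        (within_module_loading == 0 && cross_module_loading == 0))) {
    stopf("configuration error: `within_module_loading` (%g) must exceed `cross_module_loading` (%g)",
          within_module_loading, cross_module_loading)
  }
  if (n_modules > min(n_chaperones, n_clients)) {
    stopf("configuration error: `n_modules` (%d) exceeds min(n_chaperones, n_clients) = %d",
          n_modules, min(n_chaperones, n_clients))
  }
  structure(cfg, class = "synthetic_config")
}

chaperone_ids <- function(n) sprintf("CHAP%02d", seq_len(n))
client_ids <- function(n) sprintf("CLNT%03d", seq_len(n))

# Round-robin module labels: every module holds at least one member when
# n >= n_modules (mirrors the observed networks, where every module contains
# at least one chaperone).
round_robin_modules <- function(n, k) rep_len(seq_len(k), n)

#' Generate a synthetic multi-cohort expression bundle
#'
#' Draws, for each cohort and sample, one latent Gaussian factor per module.
#' A gene assigned to module k has log-expression
#' `within_module_loading * f_k + cross_module_loading * mean(f_-k) + noise`,
#' unassigned clients are noise-only, and values are exponentiated to give
#' positive FPKM-like numbers.  Chaperones are assigned to modules round-robin
#' so every module holds at least one chaperone; the trailing fraction of
#' clients is left unassigned.
#'
#' @param config a [synthetic_config()].
#' @return A `cohort_bundle`: list with `cohorts` (named list of genes x
#'   samples matrices), `chaperone_panel`, `client_panel`, and `truth` (named
#'   character vector mapping gene id to `"1"..."K"` or `"unassigned"`).
#' @export
generate_cohort_bundle <- function(config) {
  if (!inherits(config, "synthetic_config")) config <- do.call(synthetic_config, config)
  chap <- chaperone_ids(config$n_chaperones)
  clnt <- client_ids(config$n_clients)
  k <- config$n_modules

  chap_mod <- round_robin_modules(config$n_chaperones, k)
  n_unassigned <- round(config$frac_unassigned_clients * config$n_clients)
  n_assigned <- config$n_clients - n_unassigned
  clnt_mod <- c(round_robin_modules(n_assigned, k), rep(NA_integer_, n_unassigned))

  truth <- c(as.character(chap_mod), ifelse(is.na(clnt_mod), "unassigned",
                                            as.character(clnt_mod)))
  names(truth) <- c(chap, clnt)

  gene_mod <- c(chap_mod, clnt_mod)  # NA = unassigned
  genes <- c(chap, clnt)
  n_genes <- length(genes)
  n_samp <- config$n_samples_per_cohort

  # One RNG stream per bundle, split per cohort by fixed offsets so each
  # cohort's matrix is reproducible independently of generation order.
  cohort_seeds <- config$seed + 7919L * seq_len(config$n_cohorts)
  cohorts <- lapply(seq_len(config$n_cohorts), function(t) {
    with_seed(cohort_seeds[t], {
      factors <- matrix(stats::rnorm(k * n_samp), nrow = k)  # K x samples
      factor_mean <- colMeans(factors)
      y <- matrix(stats::rnorm(n_genes * n_samp, sd = config$noise_sd),
                  nrow = n_genes)
      for (g in seq_len(n_genes)) {
        m <- gene_mod[g]
        if (!is.na(m)) {
          other_mean <- if (k > 1) (factor_mean * k - factors[m, ]) / (k - 1) else 0
          y[g, ] <- y[g, ] +
            config$within_module_loading * factors[m, ] +
            config$cross_module_loading * other_mean
        }
      }
      mat <- exp(y)
      dimnames(mat) <- list(genes, sprintf("S%03d", seq_len(n_samp)))
      mat
    })
  })
  names(cohorts) <- sprintf("cohort%02d", seq_len(config$n_cohorts))

  structure(list(cohorts = cohorts,
                 chaperone_panel = chap,
                 client_panel = clnt,
                 truth = truth,
                 config = config),
            class = "cohort_bundle")
}

#' Generate a weighted bipartite network with planted modules
#'
#' Direct fixture for the community-detection and null-test stages: chaperones
#' and clients are assigned to `n_modules` round-robin; a within-module
#' chaperone x client cell receives weight `w_in` (with ±10% uniform jitter)
#' with probability `edge_prob_in`, a cross-module cell receives jittered
#' `w_out` with probability `edge_prob_out`, and all other cells are zero.
#'
#' @param n_chaperones,n_clients panel sizes.
#' @param n_modules planted module count K.
#' @param w_in,w_out within/cross-module edge weights; `w_in > w_out >= 0`
#'   plants structure, `w_in == w_out` with equal probabilities gives an
#'   exchangeable (structureless) network.
#' @param edge_prob_in,edge_prob_out edge occupancy probabilities in `[0, 1]`.
#' @param seed integer seed.
#' @return List with `matrix` (chaperone x client weight matrix) and `truth`
#'   (named character module labels for all nodes).
#' @export
generate_planted_network <- function(n_chaperones, n_clients, n_modules,
                                     w_in, w_out,
                                     edge_prob_in, edge_prob_out,
                                     seed) {
  if (!(w_in >= w_out && w_out >= 0)) {
    stopf("require w_in >= w_out >= 0 (got w_in = %g, w_out = %g)", w_in, w_out)
  }
  if (!is_prob(edge_prob_in) || !is_prob(edge_prob_out)) {
    stopf("edge probabilities must lie in [0, 1]")
  }
  if (n_modules > min(n_chaperones, n_clients)) {
    stopf("`n_modules` (%d) exceeds min(n_chaperones, n_clients) = %d",
          n_modules, min(n_chaperones, n_clients))
  }
  chap <- chaperone_ids(n_chaperones)
  clnt <- client_ids(n_clients)
  chap_mod <- round_robin_modules(n_chaperones, n_modules)
  clnt_mod <- round_robin_modules(n_clients, n_modules)

  with_seed(seed, {
    same <- outer(chap_mod, clnt_mod, `==`)
    prob <- ifelse(same, edge_prob_in, edge_prob_out)
    base <- ifelse(same, w_in, w_out)
    present <- matrix(stats::runif(length(prob)) < prob, nrow = n_chaperones)
    jitter <- matrix(stats::runif(length(prob), 0.9, 1.1), nrow = n_chaperones)
    w <- ifelse(present, base * jitter, 0)
    dimnames(w) <- list(chap, clnt)
    truth <- c(as.character(chap_mod), as.character(clnt_mod))
    names(truth) <- c(chap, clnt)
    list(matrix = w, truth = truth)
  })
}

#' Write a cohort bundle to disk as plain-text artifacts
#'
#' Each cohort is written as a TSV (gene id first column, sample columns,
#' header row), panels as one-gene-per-line text files, and truth labels as a
#' two-column TSV.
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if missing).
#' @return Invisibly, a named list of written paths.
#' @export
write_cohort_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (nm in names(bundle$cohorts)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write_expression_tsv(bundle$cohorts[[nm]], p)
    paths$cohorts <- c(paths$cohorts, p)
  }
  paths$chaperones <- file.path(dir, "chaperones.txt")
  writeLines(bundle$chaperone_panel, paths$chaperones)
  paths$clients <- file.path(dir, "clients.txt")
  writeLines(bundle$client_panel, paths$clients)
  paths$truth <- file.path(dir, "truth.tsv")
  utils::write.table(
    data.frame(gene = names(bundle$truth), module = unname(bundle$truth)),
    paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
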