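# End-to-end orchestration: correlate -> filter -> aggregate -> network ->
# detect -> null test -> cluster -> client-set partitions, with every
# intermediate written to disk and a manifest recording seeds and digests.

#' Pipeline configuration
#'
#' Inputs are either a [synthetic_config()] (`synthetic`) or paths to
#' already-downloaded cohort TSVs plus two panel files.  The defaults
#' reproduce the study's stated settings: family-wise alpha 0.05
#' (Bonferroni-corrected by the panel product), 1000 randomisations, 13
#' synthetic cohorts.
#'
#' @param synthetic a [synthetic_config()], or `NULL` when reading files.
#' @param cohort_paths character vector of expression TSV paths.
#' @param chaperone_path,client_path panel files (one gene per line).
#' @param alpha family-wise error rate before Bonferroni correction.
#' @param n_sim null-ensemble replicates.
#' @param n_restarts community-detection restarts.
#' @param n_trades_factor curveball trades per chaperone row.
#' @param direction p-value direction, see [null_ensemble_test()].
#' @param seed master seed.
#' @param out_dir output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = NULL,
                            cohort_paths = NULL,
                            chaperone_path = NULL,
                            client_path = NULL,
                            alpha = 0.05,
                            n_sim = 1000,
                            n_restarts = 10,
                            n_trades_factor = 5,
                            direction = "random_at_least_as_good",
                            seed = 1,
                            out_dir = "results") {
  if (is.null(synthetic) &&
      (is.null(cohort_paths) || is.null(chaperone_path) || is.null(client_path))) {
    stopf("provide either `synthetic` or cohort/panel paths")
  }
  structure(list(synthetic = synthetic, cohort_paths = cohort_paths,
                 chaperone_path = chaperone_path, client_path = client_path,
                 alpha = alpha, n_sim = n_sim, n_restarts = n_restarts,
                 n_trades_factor = n_trades_factor, direction = direction,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order, writes each intermediate artifact under
#' `config$out_dir`, and returns (and writes) a manifest with seeds, input
#' digests, per-stage outputs and headline numbers.  Re-running with the same
#' config and seed reproduces every artifact byte-for-byte.  A stage failure
#' halts the run with the stage name; partial outputs are retained next to a
#' `.failed` marker.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage log lines (stderr).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) {
    if (!quiet) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                sprintf(...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(name, conditionMessage(e)), file.path(out, ".failed"))
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  manifest <- list(seed = config$seed, alpha = config$alpha,
                   n_sim = config$n_sim, n_restarts = config$n_restarts,
                   n_trades_factor = config$n_trades_factor,
                   direction = config$direction,
                   outputs = list(), inputs = list())

  # -- inputs ----------------------------------------------------------------
  log_stage("loading inputs")
  dat <- stage("inputs", {
    if (!is.null(config$synthetic)) {
      bundle <- generate_cohort_bundle(config$synthetic)
      list(cohorts = bundle$cohorts,
           chaperones = bundle$chaperone_panel,
           clients = bundle$client_panel,
           truth = bundle$truth)
    } else {
      cohorts <- lapply(config$cohort_paths, read_expression_tsv)
      names(cohorts) <- sub("\\.tsv$", "", basename(config$cohort_paths))
      manifest$inputs$digests <- as.list(tools::md5sum(config$cohort_paths))
      list(cohorts = cohorts,
           chaperones = read_panel(config$chaperone_path),
           clients = read_panel(config$client_path),
           truth = NULL)
    }
  })
  manifest$inputs$n_cohorts <- length(dat$cohorts)
  manifest$inputs$n_chaperones <- length(dat$chaperones)
  manifest$inputs$n_clients <- length(dat$clients)

  alpha_corr <- bonferroni_alpha(config$alpha, length(dat$chaperones),
                                 length(dat$clients))
  manifest$alpha_corrected <- alpha_corr

  # -- correlate + filter ----------------------------------------------------
  log_stage("correlating %d cohorts", length(dat$cohorts))
  filt <- stage("correlate", {
    lapply(names(dat$cohorts), function(nm) {
      res <- spearman_panel(dat$cohorts[[nm]], dat$chaperones, dat$clients,
                            cohort_id = nm)
      f <- filter_correlations(res, alpha_corr)
      write_correlations_tsv(res, f,
        path_long = file.path(out, paste0("correlations_", nm, ".tsv")))
      f
    })
  })
  filt_cc <- stage("correlate_chaperones", {
    alpha_cc <- bonferroni_alpha(config$alpha, length(dat$chaperones),
                                 length(dat$chaperones))
    lapply(names(dat$cohorts), function(nm) {
      filter_correlations(
        spearman_panel(dat$cohorts[[nm]], dat$chaperones, dat$chaperones,
                       cohort_id = nm),
        alpha_cc)
    })
  })

  # -- aggregate -------------------------------------------------------------
  log_stage("aggregating medians")
  pc <- stage("aggregate", aggregate_median(filt))
  pc_cc <- stage("aggregate", aggregate_median(filt_cc))
  write_pancancer(pc,
                  path_wide = file.path(out, "pancancer_matrix.tsv"),
                  path_long = file.path(out, "pancancer_long.tsv"),
                  path_summary = file.path(out, "degree_summary.json"))
  ds <- degree_summary(pc)

  # -- network + communities -------------------------------------------------
  log_stage("building network and detecting communities")
  net <- stage("network", build_network(pc))
  det <- stage("detect", detect_communities(net, n_restarts = config$n_restarts,
                                            seed = config$seed))
  mod_names <- name_modules(net, det$partition)
  write_network_tsv(net, det$partition,
                    path_edges = file.path(out, "network_edges.tsv"),
                    path_nodes = file.path(out, "network_nodes.tsv"))
  write_partition_json(det$partition, det$score,
                       file.path(out, "partition.json"),
                       module_names = mod_names)

  # -- null test -------------------------------------------------------------
  log_stage("null ensemble (%d replicates)", config$n_sim)
  nt <- stage("nulltest", null_ensemble_test(
    net, n_sim = config$n_sim, n_restarts = config$n_restarts,
    seed = config$seed, direction = config$direction,
    n_trades_factor = config$n_trades_factor))
  write_nulltest_json(nt, file.path(out, "nulltest.json"),
                      path_sims = file.path(out, "nulltest_L_sims.tsv"))

  # -- clustering ------------------------------------------------------------
  log_stage("clustering profiles")
  stage("cluster", {
    dend_cc <- cluster_profiles(pc_cc$w_med, axis = "chaperone_by_chaperone")
    write_dendrogram(dend_cc,
                     path_newick = file.path(out, "chaperone_chaperone.nwk"),
                     path_merges = file.path(out, "chaperone_chaperone_merges.tsv"))
    if (ncol(pc$w_med) >= 2) {
      dend_ck <- cluster_profiles(pc$w_med, axis = "chaperone_by_client")
      write_dendrogram(dend_ck,
                       path_newick = file.path(out, "chaperone_client.nwk"),
                       path_merges = file.path(out, "chaperone_client_merges.tsv"))
    }
  })

  # -- client-set partition for the two busiest chaperones -------------------
  top2 <- names(sort(ds$per_chaperone_client_count, decreasing = TRUE))[1:2]
  venn <- stage("venn", client_set_partition(pc, top2[1], top2[2]))
  write_client_sets(venn,
                    path_json = file.path(out, "client_sets.json"),
                    path_tsv = file.path(out, "client_sets.tsv"))

  # -- manifest --------------------------------------------------------------
  manifest$results <- list(
    n_interactions = ds$n_interactions,
    n_interacting_proteins = ds$n_interacting_proteins,
    n_modules = det$partition$n_modules,
    module_names = as.list(mod_names),
    L_obs = nt$L_obs,
    p_value = nt$p_value,
    venn = as.list(venn$counts),
    venn_chaperones = top2)
  files <- list.files(out, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$outputs <- as.list(tools::md5sum(files))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("done: %d modules, p %s", det$partition$n_modules,
            format(nt$p_value))
  invisible(manifest)
}
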