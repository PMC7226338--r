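test_that("average linkage reproduces hand-computed merge heights", {
  # d(A,B) = 0.1, d(A,C) = d(B,C) = 0.9 on a 1 - w chaperone matrix
  w <- 1 - rbind(c(0, 0.1, 0.9),
                 c(0.1, 0, 0.9),
                 c(0.9, 0.9, 0))
  dimnames(w) <- list(c("A", "B", "C"), c("A", "B", "C"))
  dend <- cluster_profiles(w, axis = "chaperone_by_chaperone")
  hc <- dend$hclust
  expect_equal(hc$height, c(0.1, 0.9), tolerance = 1e-12)
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_identical(first, c("A", "B"))
})

test_that("identical profiles merge at height zero; constant profiles are flagged", {
  w <- rbind(c(0.5, 0.2, 0.9), c(0.5, 0.2, 0.9), c(0.1, 0.8, 0.3),
             c(0.4, 0.4, 0.4))
  dimnames(w) <- list(c("A", "B", "C", "FLAT"), c("p1", "p2", "p3"))
  dend <- cluster_profiles(w, axis = "chaperone_by_client")
  expect_identical(dend$flagged, "FLAT")
  dm <- as.matrix(dend$distance)
  expect_equal(dm["A", "B"], 0, tolerance = 1e-12)
  expect_true(all(dm["FLAT", c("A", "B", "C")] == 1))
})

test_that("dendrograms are invariant to input row order and serialise to Newick", {
  w <- withr::with_seed(19, {
    m <- matrix(stats::runif(5 * 8), 5, 8,
                dimnames = list(paste0("c", 1:5), paste0("p", 1:8)))
    m
  })
  d1 <- cluster_profiles(w, axis = "chaperone_by_client")
  d2 <- cluster_profiles(w[sample(5), ], axis = "chaperone_by_client")
  expect_equal(d1$hclust$height, d2$hclust$height, tolerance = 1e-12)
  expect_equal(stats::cophenetic(d1$hclust), stats::cophenetic(d2$hclust),
               tolerance = 1e-12)
  nwk <- withr::local_tempfile(fileext = ".nwk")
  mrg <- withr::local_tempfile(fileext = ".tsv")
  tree <- write_dendrogram(d1, path_newick = nwk, path_merges = mrg)
  back <- ape::read.tree(nwk)
  expect_setequal(back$tip.label, rownames(w))
  expect_identical(nrow(utils::read.delim(mrg)), 4L)
})

test_that("average-linkage heights are monotone along rootward paths", {
  for (s in 1:5) {
    w <- withr::with_seed(s, matrix(stats::runif(6 * 10), 6, 10,
                                    dimnames = list(paste0("c", 1:6),
                                                    paste0("p", 1:10))))
    hc <- cluster_profiles(w, axis = "chaperone_by_client")$hclust
    expect_true(all(diff(hc$height) >= -1e-12))
  }
})

test_that("chaperones sharing a planted module are mutual nearest neighbours", {
  cfg <- synthetic_config(n_cohorts = 3, n_samples_per_cohort = 150,
                          n_chaperones = 6, n_clients = 24, n_modules = 3,
                          within_module_loading = 0.9,
                          cross_module_loading = 0.05,
                          frac_unassigned_clients = 0, noise_sd = 0.3,
                          seed = 23)
  b <- generate_cohort_bundle(cfg)
  filt <- lapply(names(b$cohorts), function(nm) {
    filter_correlations(
      spearman_panel(b$cohorts[[nm]], b$chaperone_panel, b$client_panel,
                     cohort_id = nm),
      bonferroni_alpha(0.05, 6, 24))
  })
  pc <- aggregate_median(filt)
  dend <- cluster_profiles(pc$w_med, axis = "chaperone_by_client")
  dm <- as.matrix(dend$distance)
  diag(dm) <- Inf
  truth <- b$truth[b$chaperone_panel]
  for (ch in b$chaperone_panel) {
    nn <- names(which.min(dm[ch, ]))
    expect_identical(unname(truth[nn]), unname(truth[ch]))
  }
})

test_that("client-set partition splits the panel into four disjoint sets", {
  w <- rbind(c(0.5, 0.4, 0, 0), c(0.6, 0, 0.7, 0))
  dimnames(w) <- list(c("A", "B"), c("c1", "c2", "c3", "c4"))
  csp <- client_set_partition(w, "A", "B")
  expect_identical(csp$both, "c1")
  expect_identical(csp$only_a, "c2")
  expect_identical(csp$only_b, "c3")
  expect_identical(csp$neither, "c4")
  all_sets <- c(csp$both, csp$only_a, csp$only_b, csp$neither)
  expect_identical(sort(all_sets), colnames(w))
  expect_error(client_set_partition(w, "A", "nope"), "unknown chaperone")

  # extreme case: one all-positive row, one all-zero row
  w2 <- rbind(rep(0.5, 4), rep(0, 4))
  dimnames(w2) <- dimnames(w)
  csp2 <- client_set_partition(w2, "A", "B")
  expect_identical(csp2$only_a, colnames(w2))
  expect_length(csp2$both, 0)
})

test_that("client-set counts tie to degrees and the partition is symmetric", {
  for (s in 1:5) {
    w <- withr::with_seed(s, {
      m <- matrix(stats::runif(3 * 12), 3, 12,
                  dimnames = list(paste0("ch", 1:3), paste0("p", 1:12)))
      m[m < 0.4] <- 0
      m
    })
    csp <- client_set_partition(w, "ch1", "ch2")
    deg <- degree_summary(w)$per_chaperone_client_count
    expect_equal(length(csp$both) + length(csp$only_a), unname(deg["ch1"]))
    expect_equal(length(csp$both) + length(csp$only_b), unname(deg["ch2"]))
    swapped <- client_set_partition(w, "ch2", "ch1")
    expect_identical(swapped$only_a, csp$only_b)
    expect_identical(swapped$only_b, csp$only_a)
    expect_identical(swapped$both, csp$both)
    expect_identical(swapped$neither, csp$neither)
  }
})

test_that("client-set JSON/TSV exports carry the counts", {
  w <- rbind(c(0.5, 0.4, 0, 0), c(0.6, 0, 0.7, 0))
  dimnames(w) <- list(c("A", "B"), c("c1", "c2", "c3", "c4"))
  csp <- client_set_partition(w, "A", "B")
  js <- withr::local_tempfile(fileext = ".json")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_client_sets(csp, path_json = js, path_tsv = tsv)
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(back$counts$both, 1)
  tab <- utils::read.delim(tsv)
  expect_identical(tab$set, c("both", "only_a", "only_b", "neither"))
  expect_identical(sum(tab$count), 4L)
})
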