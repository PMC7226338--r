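make_expr <- function(mat, genes, samples = NULL) {
  dimnames(mat) <- list(genes, samples %||% sprintf("S%d", seq_len(ncol(mat))))
  mat
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("perfect monotone and anti-monotone pairs hit r = +/-1", {
  expr <- make_expr(rbind(c(1, 2, 3, 4, 5),
                          c(2, 4, 6, 8, 10),
                          c(10, 8, 6, 4, 2)),
                    c("chap", "up", "down"))
  res <- spearman_panel(expr, "chap", c("up", "down"))
  expect_equal(unname(res$r["chap", "up"]), 1)
  expect_equal(unname(res$r["chap", "down"]), -1)
  expect_equal(unname(res$p["chap", c("up", "down")]), c(0, 0))
})

test_that("ties get average ranks and the t-approximation tracks the exact permutation p", {
  # x = [1,2,2,3] ranks to [1, 2.5, 2.5, 4]
  expect_equal(rank(c(1, 2, 2, 3)), c(1, 2.5, 2.5, 4))
  x <- c(1, 2, 2, 3, 5, 5, 6, 7)
  pairs <- withr::with_seed(21, {
    lapply(1:5, function(i) stats::runif(8))
  })
  p_t <- p_exact <- numeric(length(pairs))
  for (i in seq_along(pairs)) {
    expr <- make_expr(rbind(x, pairs[[i]]), c("chap", "cl"))
    res <- spearman_panel(expr, "chap", "cl")
    p_t[i] <- res$p["chap", "cl"]
    p_exact[i] <- perm_spearman_p(x, pairs[[i]])
  }
  # the approximation and the exhaustive 8!-permutation oracle order pairs
  # identically
  expect_identical(order(p_t), order(p_exact))
})

test_that("panel Spearman agrees with the reference rank-correlation routine", {
  expr <- withr::with_seed(4, {
    make_expr(matrix(stats::rexp(8 * 20), 8), paste0("g", 1:8))
  })
  res <- spearman_panel(expr, paste0("g", 1:3), paste0("g", 4:8))
  ref <- stats::cor(t(expr), method = "spearman")[1:3, 4:8]
  expect_equal(unname(res$r), unname(ref), tolerance = 1e-12)
  # and the p-value matches cor.test's t-approximation cell by cell
  ct <- stats::cor.test(expr["g2", ], expr["g6", ], method = "spearman",
                        exact = FALSE)
  expect_equal(unname(res$p["g2", "g6"]), ct$p.value, tolerance = 1e-12)
})

test_that("constant genes, self-pairs and missing genes follow the contract", {
  expr <- make_expr(rbind(c(1, 2, 3, 4), c(5, 5, 5, 5), c(4, 3, 2, 1)),
                    c("chap", "flat", "cl"))
  res <- spearman_panel(expr, c("chap", "cl"), c("flat", "cl"))
  expect_equal(unname(res$r["chap", "flat"]), 0)
  expect_equal(unname(res$p["chap", "flat"]), 1)
  expect_identical(res$constant_genes, "flat")
  # self-pair flagged with r = 1, p = 0
  expect_true(res$self_pairs["cl", "cl"])
  expect_equal(unname(res$r["cl", "cl"]), 1)

  expect_error(spearman_panel(expr, "nope", "cl"), "missing")
  expect_warning(res2 <- spearman_panel(expr, c("chap", "nope"), "cl",
                                        missing_ok = TRUE), "dropping")
  expect_identical(rownames(res2$r), "chap")
  expect_error(spearman_panel(expr[, 1:2], "chap", "cl"), ">= 3 samples")
})

test_that("bonferroni_alpha divides by the panel product", {
  expect_equal(bonferroni_alpha(0.05, 15, 1142), 0.05 / 17130)
  expect_equal(bonferroni_alpha(0.05, 1, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 5, 10), 0.001)
  expect_error(bonferroni_alpha(0, 5, 10), "alpha")
  expect_error(bonferroni_alpha(0.05, 0, 10), "positive integer")
})

test_that("filtering zeroes negative, non-significant and self pairs", {
  r <- matrix(c(-0.99, 0.9, 0.9, 0.3), 2, 2,
              dimnames = list(c("c1", "c2"), c("p1", "p2")))
  p <- matrix(c(1e-10, 1e-8, 1e-5, 0.5), 2, 2, dimnames = dimnames(r))
  res <- structure(list(cohort_id = "x", r = r, p = p, n_samples = 100,
                        constant_genes = character(),
                        self_pairs = matrix(FALSE, 2, 2, dimnames = dimnames(r))),
                   class = "correlation_result")
  f <- filter_correlations(res, 2.9e-6)
  # only the cell with r = 0.9, p = 1e-8 clears both gates
  expect_equal(unname(f$w), rbind(c(0, 0), c(0.9, 0)))
  # all nonzero w equal the corresponding r
  expect_true(all(f$w[f$w > 0] == r[f$w > 0]))
  # zero-density grows as the threshold tightens
  f_loose <- filter_correlations(res, 0.9)
  expect_gte(sum(f$w == 0), sum(f_loose$w == 0))
})

test_that("the filtered weights are rank-invariant under monotone transforms", {
  expr <- withr::with_seed(8, {
    make_expr(matrix(stats::rexp(6 * 30), 6), paste0("g", 1:6))
  })
  chap <- paste0("g", 1:2); cl <- paste0("g", 3:6)
  a <- filter_correlations(spearman_panel(expr, chap, cl), 0.05)
  b <- filter_correlations(spearman_panel(expr^3 + 1, chap, cl), 0.05)
  expect_equal(a$w, b$w, tolerance = 1e-12)
})

test_that("duplicate gene ids are a hard error unless deduped", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS2\tS3", "g1\t1\t2\t3", "g1\t3\t2\t1", "g2\t5\t6\t7"), tmp)
  expect_error(read_expression_tsv(tmp), "duplicate")
  expect_warning(m <- read_expression_tsv(tmp, dedupe_first = TRUE), "duplicate")
  expect_equal(unname(m["g1", ]), c(1, 2, 3))
})

test_that("long/wide TSV serialisation round-trips bit-stably", {
  expr <- withr::with_seed(13, {
    make_expr(matrix(stats::rexp(5 * 25), 5), paste0("g", 1:5))
  })
  res <- spearman_panel(expr, paste0("g", 1:2), paste0("g", 3:5))
  f <- filter_correlations(res, 0.05)
  tmp_w <- withr::local_tempfile(fileext = ".tsv")
  write_correlations_tsv(res, f, path_wide = tmp_w)
  expect_equal(mitochapnet:::read_matrix_tsv(tmp_w), f$w, tolerance = 0)
})
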