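test_that("expression tables round-trip through write and read", {
  recs <- list(
    simulate_gene(mechanism_spec("simple"), p53_osc_ref(), p53_rise_ref(),
                  noise_model(0), gene_id = "gA"),
    simulate_gene(mechanism_spec("simple", kinetic_params(kd_mrna = 0.8)),
                  p53_osc_ref(), p53_rise_ref(), noise_model(0),
                  gene_id = "gB"))
  tab <- records_table(recs, "mRNA")
  expect_equal(nrow(tab), 2 * 2 * 2)   # genes x conditions x replicates
  path <- withr::local_tempfile(fileext = ".csv")
  write_expression_table(tab, path)
  back <- read_expression_table(path, "mRNA")
  expect_equal(attr(back, "times"), attr(tab, "times"))
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
})

test_that("reader validates structure and values", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene_id,condition,replicate,0,1",
               "g1,oscillatory,1,1,-2"), path)
  expect_error(read_expression_table(path), "negative levels in rows: 1")
  writeLines(c("gene_id,condition,replicate,0,1",
               "g1,oscillatory,1,1,2",
               "g1,oscillatory,1,1,3"), path)
  expect_error(read_expression_table(path), "duplicate")
  writeLines(c("gene_id,condition,replicate,0,1",
               "g1,sustained,1,1,2"), path)
  expect_error(read_expression_table(path), "oscillatory")
  writeLines(c("gene_id,replicate,0,1", "g1,1,1,2"), path)
  expect_error(read_expression_table(path), "condition")
})

test_that("fold change divides the replicate mean by its basal value", {
  expect_equal(fold_change(c(2, 4, 6)), c(1, 2, 3))
  expect_equal(fold_change(rbind(c(1, 2), c(3, 6))), c(1, 2))
  expect_equal(fold_change(rep(5, 4)), rep(1, 4))
  expect_error(fold_change(c(0, 1)), "basal")
})

test_that("max fold change respects the 1-9 h window", {
  times <- default_grid()
  fc <- c(1, rep(1.1, 9), 5)          # peaks only at 24 h
  expect_equal(max_fold_change(fc, times), 1.1)
  expect_equal(max_fold_change(c(1, 1.4, 2.1, 1.2), 0:3, window = c(1, 3)),
               2.1)
  expect_equal(max_fold_change(rep(1, 11), times), 1)
  expect_error(max_fold_change(fc, times, window = c(30, 40)), "window")
})

test_that("fold change then max fold change is scale invariant", {
  set.seed(4)
  for (i in 1:10) {
    x <- runif(11, 0.5, 5)
    a <- max_fold_change(fold_change(x), default_grid())
    b <- max_fold_change(fold_change(x * runif(1, 0.1, 100)), default_grid())
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("z-scores have mean 0, sd 1, and affine invariance", {
  times <- default_grid()
  set.seed(5)
  x <- runif(11)
  z <- zscore_trace(x, times)
  expect_equal(length(z), 10)          # 24 h point excluded
  expect_lt(abs(mean(z)), 1e-9)
  expect_equal(stats::sd(z), 1, tolerance = 1e-9)
  expect_equal(z, zscore_trace(3.7 * x + 2, times), tolerance = 1e-9)
  expect_equal(zscore_trace(c(1, 2, 3), 0:2), c(-1, 0, 1))
  expect_warning(zc <- zscore_trace(rep(2, 11), times), "constant")
  expect_equal(zc, rep(0, 10))
})

test_that("replicate correlation matches the covariance formula", {
  set.seed(6)
  for (i in 1:10) {
    a <- rnorm(11)
    b <- rnorm(11)
    oracle <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(replicate_correlation(a, b), oracle, tolerance = 1e-12)
  }
  x <- rnorm(11)
  expect_equal(replicate_correlation(x, x), 1)
  expect_equal(replicate_correlation(x, -x + 3), -1)
  expect_error(replicate_correlation(x, rep(1, 11)), "variance")
  expect_error(replicate_correlation(x, x[1:5]), "grids")
})
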