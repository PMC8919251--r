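test_that("diff scores match their worked values", {
  times <- 0:9
  x <- 1 + times / 5
  expect_equal(diff_score(x, x, times, "late"), 0)
  expect_equal(diff_score(x, x, times, "early"), 0)
  # oscillatory at exactly half the rising normalised level over 3-9 h
  rise <- c(1, 1, 1, 2, 2, 2, 2, 2, 2, 2)
  osc <- c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1)
  expect_equal(diff_score(osc, rise, times, "late"), 7 * 0.5)
  # basal normalisation: rescaling either trace changes nothing
  expect_equal(diff_score(3 * osc, rise, times, "late"), 3.5)
  expect_error(diff_score(c(0, 1), c(1, 1), 0:1), "basal")
})

test_that("diff agrees with a term-by-term summation oracle", {
  set.seed(12)
  times <- default_grid()
  for (i in 1:20) {
    a <- runif(11, 0.5, 3)
    b <- runif(11, 0.5, 3)
    for (win in list(c(3, 9), c(0, 3))) {
      idx <- which(times >= win[1] & times <= win[2])
      oracle <- 0
      for (j in idx) oracle <- oracle + (1 - (a[j] / a[1]) / (b[j] / b[1]))
      expect_equal(diff_score(a, b, times, win), oracle, tolerance = 1e-12)
    }
  }
})

test_that("swapping conditions maps each diff term 1 - r to 1 - 1/r", {
  set.seed(13)
  times <- 0:9
  a <- runif(10, 0.5, 3); b <- runif(10, 0.5, 3)
  idx <- which(times >= 3 & times <= 9)
  r <- (a[idx] / a[1]) / (b[idx] / b[1])
  expect_equal(diff_score(a, b, times, "late"), sum(1 - r))
  expect_equal(diff_score(b, a, times, "late"), sum(1 - 1 / r))
})

test_that("the 3 h point is shared by both windows as printed", {
  times <- 0:9
  osc <- rep(1, 10)
  rise <- rep(1, 10); rise[4] <- 2     # only t = 3 h differs
  expect_equal(diff_score(osc, rise, times, "late"), 0.5)
  expect_equal(diff_score(osc, rise, times, "early"), 0.5)
})

test_that("diff ranking is a stable descending sort with id tie-breaks", {
  d <- c(g2 = 1, g1 = 1, g3 = 5)
  expect_equal(rank_by_diff(d), c("g3", "g1", "g2"))
  expect_equal(rank_by_diff(d[c(3, 1, 2)]), c("g3", "g1", "g2"))
  # uniformly higher rising expression gives all-positive diffs
  po <- p53_osc_ref(); pr <- p53_rise_ref()
  m_o <- simulate_mrna(po$levels, 1, 0.6)
  m_r <- simulate_mrna(pr$levels, 1, 0.6)
  p_o <- simulate_protein(m_o, 1, 0.3)
  p_r <- simulate_protein(m_r, 1, 0.3)
  expect_gt(diff_score(p_o, p_r, hourly, "late"), 0)
})

test_that("a file-based functional annotation feeds the class comparison", {
  ann_df <- utils::read.csv(test_path("annotation_synthetic.csv"))
  ann <- setNames(ann_df$class, ann_df$gene_id)
  expect_setequal(unique(ann), c("antiproliferative", "other"))
  set.seed(16)
  fc <- setNames(rlnorm(length(ann), 0.3, 0.2), names(ann))
  cc <- class_comparison(fc, ann)
  expect_equal(unname(cc$n),
               as.vector(table(ann)[c("antiproliferative", "other")]))
  expect_true(cc$p >= 0 && cc$p <= 1)
})

test_that("class comparison is calibrated under the null and powered", {
  fc <- setNames(rep(2, 20), paste0("g", 1:20))
  ann <- setNames(rep(c("antiproliferative", "other"), each = 10),
                  names(fc))
  same <- class_comparison(fc, ann)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  set.seed(14)
  null_p <- replicate(1000, {
    x <- setNames(rnorm(60), paste0("g", 1:60))
    a <- setNames(rep(c("antiproliferative", "other"), each = 30), names(x))
    class_comparison(x, a)$p
  })
  rate <- mean(null_p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
  power_p <- replicate(200, {
    x <- setNames(c(rnorm(50, 1), rnorm(50, 0)), paste0("g", 1:100))
    a <- setNames(rep(c("antiproliferative", "other"), each = 50), names(x))
    class_comparison(x, a)$p
  })
  expect_gte(mean(power_p < 0.05), 0.8)
  expect_error(class_comparison(fc[1:3],
                                setNames(c("antiproliferative", "other",
                                           "other"), names(fc)[1:3])),
               "two genes")
})
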