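test_that("mRNA recursion matches closed forms", {
  p53 <- rep(2, 25)
  # pure decay when production is off
  m <- simulate_mrna(p53, 0, 0.3, mrna0 = 1)
  expect_equal(m, (1 - 0.3)^(0:24), tolerance = 1e-12)
  # kd = 1 with no production: gone after one step
  expect_equal(simulate_mrna(p53, 0, 1, mrna0 = 5)[-1], rep(0, 24))
  # constant input converges to kp * P / kd (brute-force long iteration)
  long <- simulate_mrna(rep(2, 500), 0.7, 0.2, mrna0 = 0)
  expect_equal(long[500], 0.7 * 2 / 0.2, tolerance = 1e-8)
  # steady-state initial condition is a fixed point
  expect_equal(simulate_mrna(p53, 0.7, 0.2), rep(0.7 * 2 / 0.2, 25),
               tolerance = 1e-12)
  expect_error(simulate_mrna(p53, 1, 1.2), "kd_mrna")
})

test_that("protein recursion honours decay, steady state, and delay", {
  expect_equal(simulate_protein(rep(0, 25), 0.5, 0.4, prot0 = 1),
               (1 - 0.4)^(0:24), tolerance = 1e-12)
  long <- simulate_protein(rep(3, 400), 0.5, 0.25, prot0 = 0)
  expect_equal(long[400], 0.5 * 3 / 0.25, tolerance = 1e-8)
  # a single mRNA pulse: delay shifts the protein peak by about tdel
  mrna <- 0.2 + 3 * exp(-(0:24 - 4)^2 / 2)
  p0 <- simulate_protein(mrna, 1, 0.6, tdel = 0)
  p2 <- simulate_protein(mrna, 1, 0.6, tdel = 2)
  expect_equal(which.max(p2) - which.max(p0), 2)
  # kd -> 0 limit from an empty pool: cumulative, monotone trace
  cum <- simulate_protein(mrna, 1, 0, prot0 = 0)
  expect_true(all(diff(cum) >= 0))
  expect_equal(cum, c(0, cumsum(mrna[-1])), tolerance = 1e-12)
})

test_that("hourly recursion approaches the continuous model as dt shrinks", {
  skip_if_not_installed("deSolve")
  spec <- p53_waveform_spec("rising")
  kp <- 0.8; kd <- 0.3
  p53_fun <- function(t) p53_levels(spec, t)
  ode_fit <- deSolve::ode(
    y = c(m = kp * p53_fun(0) / kd), times = seq(0, 9, by = 0.5),
    func = function(t, y, parms) list(kp * p53_fun(t) - kd * y[1]),
    method = "lsoda")
  fine_t <- seq(0, 9, by = 0.1)
  fine <- simulate_mrna(p53_fun(fine_t), kp, kd, dt = 0.1)
  at <- match(seq(0, 9, by = 0.5), round(fine_t, 10))
  expect_equal(fine[at], unname(ode_fit[, "m"]), tolerance = 0.01)
  # the native 1 h step is a coarser but consistent approximation
  coarse <- simulate_mrna(p53_fun(0:9), kp, kd)
  expect_equal(coarse, unname(ode_fit[seq(1, 19, by = 2), "m"]),
               tolerance = 0.15)
})

test_that("fits recover their own parameters on self-generated data", {
  po <- p53_osc_ref()
  grid <- default_grid()
  idx <- match(grid, hourly)
  m <- simulate_mrna(po$levels, 1.3, 0.6)
  p <- simulate_protein(m, 0.9, 0.4, tdel = 1)
  fm <- fit_mrna(po$times, po$levels, grid, m[idx])
  expect_gte(fm$r2, 0.999)
  expect_lt(abs(fm$kd - 0.6) / 0.6, 0.05)
  expect_equal(fm$kp, 1.3, tolerance = 0.05)
  fp <- fit_protein(grid, m[idx], grid, p[idx], tdel_max = 3)
  expect_gte(fp$r2, 0.999)
  expect_lt(abs(fp$kd - 0.4) / 0.4, 0.10)
  expect_lt(abs(fp$tdel - 1), 0.5)
})

test_that("white-noise observations yield low-confidence fits, flat ones flagged", {
  po <- p53_osc_ref()
  grid <- default_grid()
  set.seed(31)
  noise <- runif(11, 0.9, 1.1)
  fm <- fit_mrna(po$times, po$levels, grid, noise)
  expect_lt(fm$r2, 0.9)
  flat <- fit_mrna(po$times, po$levels, grid, rep(2, 11))
  expect_true(flat$flagged)
  expect_true(flat$low_confidence)
  expect_equal(flat$r2, 0)
  expect_true(is.na(flat$kd))
})

test_that("the correlation objective is invariant to kp rescaling", {
  po <- p53_osc_ref()
  obs <- simulate_mrna(po$levels, 1, 0.5)
  for (kp in c(0.1, 1, 7)) {
    sim <- simulate_mrna(po$levels, kp, 0.3)
    expect_equal(stats::cor(sim, obs)^2,
                 stats::cor(simulate_mrna(po$levels, 1, 0.3), obs)^2,
                 tolerance = 1e-12)
  }
})

test_that("cross-condition prediction works for shared-parameter genes", {
  po <- p53_osc_ref(); pr <- p53_rise_ref()
  grid <- default_grid(); idx <- match(grid, hourly)
  m_o <- simulate_mrna(po$levels, 1, 0.7)
  p_o <- simulate_protein(m_o, 1, 0.45, tdel = 0.5)
  m_r <- simulate_mrna(pr$levels, 1, 0.7)
  p_r <- simulate_protein(m_r, 1, 0.45, tdel = 0.5)
  fp <- fit_protein(grid, m_o[idx], grid, p_o[idx])
  pred <- predict_cross_condition(fp, grid, m_r[idx], grid, p_r[idx])
  expect_gte(pred$r2, 0.95)
  # predicting the fitted condition itself reproduces the fit quality
  self <- predict_cross_condition(fp, grid, m_o[idx], grid, p_o[idx])
  expect_equal(self$r2, fp$r2, tolerance = 1e-6)
})

test_that("parameter sweeps separate scale (kp) from shape (kd)", {
  po <- p53_osc_ref()
  mrna_h <- simulate_mrna(po$levels, 1, 0.8)
  base <- kinetic_params(kd_prot = 0.5, tdel = 0)
  sw_kp <- parameter_sweep(mrna_h, base, "kp_prot", c(0.2, 1, 5),
                           reference = po$levels)
  z <- apply(sw_kp$traces, 1, function(x) (x - mean(x)) / stats::sd(x))
  expect_lt(max(abs(z[, 1] - z[, 2])), 1e-9)
  expect_lt(max(abs(z[, 1] - z[, 3])), 1e-9)
  sw_kd <- parameter_sweep(mrna_h, base, "kd_prot",
                           c(0.05, 0.2, 0.5, 0.9), reference = po$levels)
  expect_true(all(diff(sw_kd$metrics$oscillation_score) > 0))
})
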