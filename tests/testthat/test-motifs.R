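test_that("nulled gates reduce every motif to the simple kinetic model", {
  po <- p53_osc_ref()
  k <- kinetic_params(kd_mrna = 0.6, kd_prot = 0.3, tdel = 0.5)
  m_ref <- simulate_mrna(po$levels, k$kp_mrna, k$kd_mrna)
  p_ref <- simulate_protein(m_ref, k$kp_prot, k$kd_prot, k$tdel)
  for (lvl in c("transcriptional", "translational")) {
    thr <- simulate_threshold(po$levels, threshold_spec(0, level = lvl), k)
    expect_lt(max(abs(thr$mrna - m_ref)), 1e-9)
    expect_lt(max(abs(thr$protein - p_ref)), 1e-9)
  }
  for (lvl in c("transcriptional", "posttranscriptional")) {
    cf <- simulate_cffl(po$levels,
                        ffl_spec("coherent", lvl, y_threshold = 0), k)
    expect_lt(max(abs(cf$mrna - m_ref)), 1e-9)
    expect_lt(max(abs(cf$protein - p_ref)), 1e-9)
  }
  ifl <- simulate_iffl(po$levels,
                       ffl_spec("incoherent", "posttranscriptional",
                                y_threshold = 1, repression = 0), k)
  expect_lt(max(abs(ifl$mrna - m_ref)), 1e-9)
  expect_lt(max(abs(ifl$protein - p_ref)), 1e-9)
  expect_error(simulate_cffl(po$levels,
                             ffl_spec("incoherent", y_threshold = 1), k),
               "coherent")
  expect_error(simulate_iffl(po$levels,
                             ffl_spec("coherent", y_threshold = 1), k),
               "incoherent")
})

test_that("a threshold above both regimes blocks induction entirely", {
  po <- p53_osc_ref(); pr <- p53_rise_ref()
  tr <- p53decode::simulate_mechanism(
    mechanism_spec("threshold", kinetic_params(kd_mrna = 0.7,
                                               kd_prot = 0.2, tdel = 0.5),
                   theta = "high"),
    po$levels, pr$levels)
  ex <- exclusivity_index(tr$oscillatory$protein, tr$rising$protein, hourly)
  expect_equal(ex$label, "none")
})

test_that("a medium threshold gives exclusive induction under rising input", {
  po <- p53_osc_ref(); pr <- p53_rise_ref()
  tr <- p53decode::simulate_mechanism(
    motif_presets()$threshold_medium, po$levels, pr$levels)
  ex <- exclusivity_index(tr$oscillatory$protein, tr$rising$protein, hourly)
  expect_equal(ex$label, "rising_only")
  expect_gt(ex$margin, 0)
})

test_that("the coherent FFL is a persistence detector", {
  k <- kinetic_params(kd_mrna = 0.6, kd_prot = 0.4, tdel = 0.5)
  base_spec <- function(delay) ffl_spec("coherent", "posttranscriptional",
                                        y_production = 0.15,
                                        y_degradation = 0.1,
                                        y_delay = delay, y_threshold = 1.3)
  pulse_input <- function(width) 0.3 + 2.7 * (hourly >= 1 & hourly < 1 + width)
  min_width <- function(delay) {
    for (w in 1:14) {
      out <- simulate_cffl(pulse_input(w), base_spec(delay), k)
      fc <- max(out$protein / out$protein[1])
      if (fc > 1.15) return(w)
    }
    Inf
  }
  widths <- vapply(c(0, 2, 4), min_width, numeric(1))
  expect_true(all(is.finite(widths)))
  expect_gt(widths[1], 1)                # brief pulses rejected
  expect_true(all(diff(widths) >= 0))    # longer Y delay needs longer input
  expect_gt(widths[3], widths[1])
  # a broken AND gate (no Y production) never induces
  broken <- simulate_cffl(pulse_input(14),
                          ffl_spec("coherent", "posttranscriptional",
                                   y_production = 0, y_degradation = 0.1,
                                   y_threshold = 0.9), k)
  expect_lt(max(broken$protein / broken$protein[1]), 1.15)
})

test_that("cFFL presets induce protein under the rising regime only", {
  po <- p53_osc_ref(); pr <- p53_rise_ref()
  for (nm in c("cffl_posttranscriptional", "cffl_transcriptional")) {
    tr <- p53decode::simulate_mechanism(motif_presets()[[nm]],
                                         po$levels, pr$levels)
    ex <- exclusivity_index(tr$oscillatory$protein, tr$rising$protein,
                            hourly)
    expect_equal(ex$label, "rising_only", label = nm)
  }
})

test_that("the iFFL preset inverts the mRNA-protein relationship", {
  po <- p53_osc_ref(); pr <- p53_rise_ref()
  tr <- p53decode::simulate_mechanism(motif_presets()$iffl,
                                       po$levels, pr$levels)
  ex <- exclusivity_index(tr$oscillatory$protein, tr$rising$protein, hourly)
  expect_equal(ex$label, "osc_only")
  # mRNA induced more under rising, protein more under oscillatory
  w <- hourly >= 1 & hourly <= 9
  fc <- function(x) max(x[w] / x[1])
  expect_gt(fc(tr$rising$mrna), fc(tr$oscillatory$mrna))
  expect_gt(fc(tr$oscillatory$protein), fc(tr$rising$protein))
})

test_that("motif outputs stay non-negative and bounded for bounded input", {
  po <- p53_osc_ref()
  k <- kinetic_params(kd_mrna = 0.4, kd_prot = 0.2, tdel = 1)
  outs <- list(
    simulate_threshold(po$levels, threshold_spec(1.5), k),
    simulate_cffl(po$levels, ffl_spec("coherent", y_threshold = 0.8), k),
    simulate_iffl(po$levels, ffl_spec("incoherent", y_threshold = 0.8), k))
  for (o in outs) {
    expect_true(all(o$mrna >= 0) && all(o$protein >= 0))
    expect_true(all(is.finite(o$protein)))
    expect_lt(max(o$protein), 1e4)
  }
})

test_that("exclusivity index handles identical traces and bad basals", {
  x <- c(1, 1.5, 2, 1.5, 1)
  ex <- exclusivity_index(x, x, 0:4)
  expect_equal(ex$label, "both")
  expect_equal(ex$margin, 0)
  flat <- rep(1, 5)
  expect_equal(exclusivity_index(flat, flat, 0:4)$label, "none")
  expect_error(exclusivity_index(c(0, 1), c(1, 1), 0:1), "basal")
})
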