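#' Hill gate
#'
#' `hill(x, theta, n) = x^n / (x^n + theta^n)`, with the convention
#' `hill(x, 0, n) = 1` so that a nulled threshold reduces a gated model to
#' the plain production-degradation kinetics exactly.
#'
#' @param x input level(s).
#' @param theta half-activation threshold (>= 0).
#' @param n Hill coefficient (>= 1).
#' @return Gate values in \[0, 1\].
#' @export
hill <- function(x, theta, n = 8) {
  if (theta < 0) stop("theta must be non-negative")
  if (theta == 0) return(rep(1, length(x)))
  x^n / (x^n + theta^n)
}

#' Specify an activation threshold
#'
#' A minimal input level below which no output is produced, modelled as a
#' Hill-type gate on the production term: at the transcriptional level the
#' gate acts on p53 driving mRNA synthesis, at the translational level on
#' mRNA driving protein synthesis.
#'
#' @param theta threshold in input relative units (>= 0).
#' @param hill_n Hill coefficient (cooperativity).
#' @param level `"transcriptional"` or `"translational"`.
#' @return A list of class `threshold_spec`.
#' @export
threshold_spec <- function(theta, hill_n = 8,
                           level = c("translational", "transcriptional")) {
  if (theta < 0) stop("theta must be non-negative")
  if (hill_n < 1) stop("hill_n must be at least 1")
  structure(list(theta = theta, hill_n = hill_n, level = match.arg(level)),
            class = "threshold_spec")
}

#' Specify a feed-forward loop
#'
#' A regulator X (p53) drives the target Z directly and also drives an
#' intermediate Y with first-order kinetics and a delay. In the coherent
#' topology Y is a co-activator: Z production requires both X and Y (AND
#' gate, implemented as a product of Hill terms). In the incoherent topology
#' Y is a repressor: Z production is divisively repressed once Y rises.
#' The `level` selects whether the gate acts on mRNA synthesis
#' (transcriptional) or protein synthesis (post-transcriptional).
#'
#' @param topology `"coherent"` or `"incoherent"`.
#' @param level `"transcriptional"` or `"posttranscriptional"`.
#' @param y_production,y_degradation first-order rates for Y (per hour).
#' @param y_delay delay of Y activation behind X, hours.
#' @param y_threshold Y level at which the gate half-activates.
#' @param y_hill_n Hill coefficient of the Y gate.
#' @param repression repression strength (incoherent only; 0 disables).
#' @return A list of class `ffl_spec`.
#' @export
ffl_spec <- function(topology = c("coherent", "incoherent"),
                     level = c("posttranscriptional", "transcriptional"),
                     y_production = 0.1, y_degradation = 0.08,
                     y_delay = 1, y_threshold = 1, y_hill_n = 8,
                     repression = 19) {
  topology <- match.arg(topology)
  level <- match.arg(level)
  if (y_production < 0 || y_degradation <= 0) stop("invalid Y rates")
  if (y_delay < 0) stop("y_delay must be non-negative")
  structure(list(topology = topology, level = level,
                 y_production = y_production, y_degradation = y_degradation,
                 y_delay = y_delay, y_threshold = y_threshold,
                 y_hill_n = y_hill_n, repression = repression),
            class = "ffl_spec")
}

# First-order intermediate Y driven by X with a delay, from basal steady
# state.
simulate_y <- function(x, spec) {
  n <- length(x)
  times <- seq_len(n) - 1
  lagged <- stats::approx(times, x, xout = pmax(times - spec$y_delay, 0),
                          rule = 2)$y
  y <- numeric(n)
  y[1] <- spec$y_production * x[1] / spec$y_degradation
  if (n > 1)
    for (i in 2:n)
      y[i] <- (1 - spec$y_degradation) * y[i - 1] +
        spec$y_production * lagged[i - 1]
  y
}

# Soft-switch effective drive: above threshold the production input follows
# the activator x; below threshold it falls back to the pre-stimulus basal
# rate x0, so the gated species holds its basal steady state rather than
# decaying. hill(x, 0, n) = 1 makes the nulled gate reduce exactly to x.
switch_drive <- function(x, gate, x0 = x[1]) x * gate + x0 * (1 - gate)

# value of a trace at t - tdel, clamped to basal before t = 0
lag_trace <- function(x, tdel) {
  times <- seq_along(x) - 1
  stats::approx(times, x, xout = pmax(times - tdel, 0), rule = 2)$y
}

# protein recursion driven by an arbitrary (already lagged) input, from its
# basal steady state: p(t) = (1 - kd) p(t-1) + kp * drive(t)
protein_from_drive <- function(drive, kp, kd) {
  p <- numeric(length(drive))
  p[1] <- kp * drive[1] / kd
  for (i in seq_along(drive)[-1]) p[i] <- (1 - kd) * p[i - 1] + kp * drive[i]
  p
}

#' Simulate a gene gated by an activation threshold
#'
#' The activation threshold is a Hill gate on the production input with a
#' basal fallback: the effective drive is
#' `input * hill(input; theta, n) + input(0) * (1 - hill(input; theta, n))`,
#' i.e. below threshold the promoter (transcriptional level) or the
#' translation machinery (translational level) runs at its pre-stimulus
#' basal rate, and above threshold it follows the input. Both species
#' therefore start at, and below threshold remain at, their basal steady
#' states; with `theta = 0` the gate is fully open and the output equals
#' the plain kinetic model exactly.
#'
#' @param p53_h p53 input on an hourly grid from 0 h.
#' @param spec a [threshold_spec()].
#' @param params a [kinetic_params()].
#' @return List with `mrna` and `protein` traces on the hourly grid.
#' @export
simulate_threshold <- function(p53_h, spec, params) {
  stopifnot(inherits(spec, "threshold_spec"))
  if (spec$level == "transcriptional") {
    drive <- switch_drive(p53_h, hill(p53_h, spec$theta, spec$hill_n))
    m <- simulate_mrna(drive, params$kp_mrna, params$kd_mrna)
    p <- simulate_protein(m, params$kp_prot, params$kd_prot, params$tdel)
  } else {
    m <- simulate_mrna(p53_h, params$kp_mrna, params$kd_mrna)
    m_lag <- lag_trace(m, params$tdel)
    drive <- switch_drive(m_lag, hill(m_lag, spec$theta, spec$hill_n),
                          x0 = m[1])
    p <- protein_from_drive(drive, params$kp_prot, params$kd_prot)
  }
  list(mrna = m, protein = p)
}

#' Simulate a coherent feed-forward loop (persistence detector)
#'
#' X (p53) drives the intermediate Y and the target Z; Z production carries
#' an AND gate `hill(Y; y_threshold, n)` at the stated level, with the
#' below-threshold production falling back to the basal rate (see
#' [simulate_threshold()] for the soft-switch form). Because Y accumulates
#' slowly (and with a delay), only inputs sustained longer than Y's rise
#' time open the gate: pulsed inputs leave Z at its basal level while a
#' persistent input induces it. A nulled gate (`y_threshold = 0`)
#' reproduces the simple kinetic model exactly.
#'
#' @param x_h X (p53) input on an hourly grid from 0 h.
#' @param spec an [ffl_spec()] with coherent topology.
#' @param params a [kinetic_params()] for the target.
#' @return List with `y`, `mrna`, `protein` traces.
#' @export
simulate_cffl <- function(x_h, spec, params) {
  stopifnot(inherits(spec, "ffl_spec"))
  if (spec$topology != "coherent") stop("spec is not a coherent FFL")
  y <- simulate_y(x_h, spec)
  gate <- hill(y, spec$y_threshold, spec$y_hill_n)
  if (spec$level == "transcriptional") {
    drive <- switch_drive(x_h, gate)
    m <- simulate_mrna(drive, params$kp_mrna, params$kd_mrna)
    p <- simulate_protein(m, params$kp_prot, params$kd_prot, params$tdel)
  } else {
    m <- simulate_mrna(x_h, params$kp_mrna, params$kd_mrna)
    m_lag <- lag_trace(m, params$tdel)
    drive <- switch_drive(m_lag, gate, x0 = m[1])
    p <- protein_from_drive(drive, params$kp_prot, params$kd_prot)
  }
  list(y = y, mrna = m, protein = p)
}

#' Simulate an incoherent feed-forward loop
#'
#' X drives both the target Z and a repressor Y; Z production is divisively
#' repressed by a factor `1 + repression * hill(Y; y_threshold, n)` at the
#' stated level (translation by default). When the input is sustained, Y
#' accumulates and the repression is epistatic, suppressing the target
#' despite a strongly induced mRNA; under brief pulses Y stays below
#' threshold and the target follows its mRNA. `repression = 0` reduces to
#' simple regulation.
#'
#' @param x_h X (p53) input on an hourly grid from 0 h.
#' @param spec an [ffl_spec()] with incoherent topology.
#' @param params a [kinetic_params()] for the target.
#' @return List with `y`, `mrna`, `protein` traces.
#' @export
simulate_iffl <- function(x_h, spec, params) {
  stopifnot(inherits(spec, "ffl_spec"))
  if (spec$topology != "incoherent") stop("spec is not an incoherent FFL")
  y <- simulate_y(x_h, spec)
  rep_factor <- 1 / (1 + spec$repression *
                       hill(y, spec$y_threshold, spec$y_hill_n))
  if (spec$level == "transcriptional") {
    drive <- x_h * rep_factor
    m <- simulate_mrna(drive, params$kp_mrna, params$kd_mrna)
    p <- simulate_protein(m, params$kp_prot, params$kd_prot, params$tdel)
  } else {
    m <- simulate_mrna(x_h, params$kp_mrna, params$kd_mrna)
    drive <- lag_trace(m, params$tdel) * rep_factor
    p <- protein_from_drive(drive, params$kp_prot, params$kd_prot)
  }
  list(y = y, mrna = m, protein = p)
}

#' Exclusivity of protein induction between the two regimes
#'
#' Applies the protein induction fold-change criterion (max FC over 1-9 h
#' above `fc_threshold`) to each condition's trace and reports which regime,
#' if either, is exclusively induced, together with the margin (difference
#' of maximum fold changes, rising minus oscillatory).
#'
#' @param trace_osc,trace_rise protein traces on a shared grid.
#' @param times matching times in hours.
#' @param fc_threshold induction threshold (default 1.15).
#' @return List with `label` (`"none"`, `"osc_only"`, `"rising_only"`,
#'   `"both"`) and `margin`.
#' @export
exclusivity_index <- function(trace_osc, trace_rise, times,
                              fc_threshold = 1.15) {
  if (trace_osc[1] <= 0 || trace_rise[1] <= 0) stop("zero basal level")
  fc_o <- max_fold_change(trace_osc / trace_osc[1], times)
  fc_r <- max_fold_change(trace_rise / trace_rise[1], times)
  ind_o <- fc_o > fc_threshold
  ind_r <- fc_r > fc_threshold
  label <- if (ind_o && ind_r) "both"
  else if (ind_o) "osc_only"
  else if (ind_r) "rising_only"
  else "none"
  list(label = label, margin = fc_r - fc_o)
}
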