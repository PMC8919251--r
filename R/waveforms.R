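#' Specify a p53 input waveform
#'
#' Two stereotyped bulk p53 regimes are modelled. The oscillatory regime
#' (irradiation) is a baseline plus a train of Gaussian pulses whose
#' amplitudes decay geometrically from pulse to pulse, capturing the damped
#' second peak caused by population desynchronisation. The rising regime
#' (irradiation plus MDM2 inhibition) is a saturating exponential approach to
#' a plateau.
#'
#' Defaults: 5.5 h period, first peak at 2 h, pulse s.d. 1.0 h (narrow
#' enough that the first pulse leaks little signal into t = 0 while keeping
#' the peak-to-trough ratio of the noiseless waveform well above 3),
#' per-pulse damping 0.6. The nominal second-peak centre is therefore 7.5 h
#' (first peak + period); `first_peak_time` and `period` are both exposed so
#' a 7 h second peak can be configured instead.
#'
#' The default baselines are chosen so the two regimes share the same
#' pre-stimulus p53 level: the rising baseline (0.32) equals the oscillatory
#' waveform's value at t = 0 (its 0.12 floor plus the onset of the first
#' pulse), so cross-condition analyses start from a common basal state.
#'
#' @param kind `"oscillatory"` or `"rising"`.
#' @param period pulse period in hours (oscillatory).
#' @param first_peak_time centre of the first pulse in hours.
#' @param pulse_width Gaussian s.d. of each pulse in hours.
#' @param damping per-pulse amplitude ratio in (0, 1].
#' @param baseline basal p53 level (relative units).
#' @param amplitude amplitude of the first pulse (relative units).
#' @param rise_rate exponential rate of the rising regime (per hour).
#' @param plateau asymptotic increase above baseline of the rising regime.
#' @return An object of class `p53_waveform_spec`.
#' @export
p53_waveform_spec <- function(kind = c("oscillatory", "rising"),
                              period = 5.5, first_peak_time = 2,
                              pulse_width = 1.0, damping = 0.6,
                              baseline = NULL, amplitude = 1.5,
                              rise_rate = 0.25, plateau = 3) {
  kind <- match.arg(kind)
  if (is.null(baseline)) baseline <- if (kind == "rising") 0.32 else 0.12
  if (period <= 0) stop("period must be positive")
  if (damping <= 0 || damping > 1) stop("damping must be in (0, 1]")
  if (baseline < 0) stop("baseline must be non-negative")
  if (pulse_width <= 0) stop("pulse_width must be positive")
  structure(
    list(kind = kind, period = period, first_peak_time = first_peak_time,
         pulse_width = pulse_width, damping = damping, baseline = baseline,
         amplitude = amplitude, rise_rate = rise_rate, plateau = plateau),
    class = "p53_waveform_spec")
}

#' Evaluate a p53 waveform at arbitrary times
#'
#' @param spec a [p53_waveform_spec()].
#' @param times numeric vector of hours.
#' @return Numeric vector of p53 levels (relative units).
#' @export
p53_levels <- function(spec, times) {
  stopifnot(inherits(spec, "p53_waveform_spec"))
  if (length(times) == 0) stop("empty time vector")
  if (spec$kind == "rising") {
    return(spec$baseline + spec$plateau * (1 - exp(-spec$rise_rate * times)))
  }
  n_pulses <- max(1L, ceiling((max(times) - spec$first_peak_time) /
                                spec$period) + 1L)
  out <- rep(spec$baseline, length(times))
  for (k in seq_len(n_pulses) - 1L) {
    centre <- spec$first_peak_time + k * spec$period
    out <- out + spec$amplitude * spec$damping^k *
      exp(-(times - centre)^2 / (2 * spec$pulse_width^2))
  }
  out
}

#' Generate a p53 input time course
#'
#' @inheritParams p53_levels
#' @param times sampling grid (default [default_grid()]).
#' @param species identifier for the generated trace.
#' @return A [time_course()] holding the noiseless waveform.
#' @export
gen_p53 <- function(spec, times = default_grid(), species = "p53") {
  time_course(species, spec$kind, 1L, times, p53_levels(spec, times))
}
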