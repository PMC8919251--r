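#' Oscillation score of a trace
#'
#' Operationalises "oscillatory" dynamics: the maximum Pearson correlation,
#' over lags 0-3 h, between the z-scored 0-9 h trace and the z-scored
#' oscillatory p53 reference shifted later by the lag, plus the number of
#' interior local maxima of the (unlagged) trace in the window. Traces that
#' track the pulsed input (directly or with a short delay) score near 1;
#' monotone traces score low and show at most one interior peak.
#'
#' @param times,levels the trace (hourly within 0-9 h at least).
#' @param ref_times,ref_levels the oscillatory p53 reference.
#' @param max_lag largest lag tried, hours (integer steps).
#' @param window scoring window, default 0-9 h.
#' @return List with `score` in \[-1, 1\], `lag`, `n_peaks`.
#' @export
oscillation_score <- function(times, levels, ref_times, ref_levels,
                              max_lag = 3, window = c(0, 9)) {
  idx <- which(times >= window[1] & times <= window[2])
  x <- levels[idx]
  tx <- times[idx]
  if (stats::sd(x) == 0)
    return(list(score = 0, lag = NA_real_, n_peaks = 0L))
  ref_f <- stats::approxfun(ref_times, ref_levels, rule = 2)
  best <- -Inf
  best_lag <- 0
  for (lag in 0:max_lag) {
    r <- ref_f(tx - lag)
    if (stats::sd(r) == 0) next
    cc <- stats::cor(x, r)
    if (cc > best) {
      best <- cc
      best_lag <- lag
    }
  }
  list(score = if (is.finite(best)) best else 0, lag = best_lag,
       n_peaks = count_interior_peaks(x),
       n_extrema = count_interior_extrema(x))
}

#' Count interior local maxima of a trace
#'
#' Plateau-aware: a run of equal values higher than both flanks counts as
#' one maximum. Endpoints never count.
#'
#' @param x numeric vector.
#' @param prominence minimum rise above both flanking runs, as a fraction
#'   of the trace range (filters sampling jitter; default 0.05).
#' @return Integer count.
#' @export
count_interior_peaks <- function(x, prominence = 0.05) {
  interior_extrema(x, prominence)$maxima
}

# Interior maxima and minima after collapsing sub-prominence movement.
# The trace is simplified by keeping only points that move more than
# `prominence * range` away from the last kept point (so plateaus and
# sampling jitter collapse while slow cumulative drifts survive), then
# strict turning points of the simplified series are counted. On the
# truncated 0-9 h window an oscillation typically shows as
# peak-trough(-rise), so direction-change counting is the robust readout.
interior_extrema <- function(x, prominence = 0.05) {
  if (length(x) < 3 || diff(range(x)) == 0)
    return(list(maxima = 0L, minima = 0L))
  tol <- prominence * diff(range(x))
  keep <- x[1]
  for (v in x[-1]) if (abs(v - keep[length(keep)]) > tol)
    keep <- c(keep, v)
  n <- length(keep)
  if (n < 3) return(list(maxima = 0L, minima = 0L))
  mid <- keep[2:(n - 1)]
  maxima <- sum(mid > keep[1:(n - 2)] & mid > keep[3:n])
  minima <- sum(mid < keep[1:(n - 2)] & mid < keep[3:n])
  list(maxima = as.integer(maxima), minima = as.integer(minima))
}

#' Count interior direction changes (maxima plus minima) of a trace
#'
#' The oscillation criterion used for class assignment: on a window that
#' truncates the second pulse (0-9 h), an oscillatory trace shows a peak
#' followed by a trough even when its second peak falls on the window edge,
#' so peaks and troughs both count as evidence of non-monotonicity.
#'
#' @inheritParams count_interior_peaks
#' @return Integer count of prominent interior maxima plus minima.
#' @export
count_interior_extrema <- function(x, prominence = 0.05) {
  e <- interior_extrema(x, prominence)
  e$maxima + e$minima
}

#' The mRNA-by-protein dynamical category lookup table
#'
#' A fixed 4 x 6 lookup from (mRNA class, protein class) to a category
#' letter. Eleven cells correspond to observed response combinations
#' (letters a-k); the remaining cells are marked `"unobserved*"` because
#' they cannot arise without additional feedback mechanisms independent of
#' the input dynamics. A lack of protein induction (category k) can occur
#' under every mRNA class, so the `not_induced` column maps to k throughout.
#'
#' @return A character matrix with mRNA classes in rows and protein classes
#'   in columns.
#' @export
category_lookup <- function() {
  mrna <- c("osc_induced_both", "nonosc_induced_both", "rising_only",
            "osc_only")
  prot <- c("oscillatory", "rise_both", "rise_and_decrease", "rising_only",
            "osc_only", "not_induced")
  m <- matrix("unobserved*", 4, 6, dimnames = list(mrna, prot))
  m["osc_induced_both", ] <- c("a", "b", "c", "d", "h", "k")
  m["nonosc_induced_both", c("rise_both", "rise_and_decrease",
                             "rising_only", "not_induced")] <-
    c("e", "f", "g", "k")
  m["rising_only", c("rising_only", "not_induced")] <- c("j", "k")
  m["osc_only", c("osc_only", "not_induced")] <- c("i", "k")
  m
}

#' Assign the dynamical category letter
#'
#' Pure total lookup into [category_lookup()].
#'
#' @param mrna_class one of the four mRNA classes.
#' @param prot_class one of the six protein classes.
#' @return A category letter (`"a"`-`"k"`) or `"unobserved*"`.
#' @export
assign_category <- function(mrna_class, prot_class) {
  lut <- category_lookup()
  if (!mrna_class %in% rownames(lut)) stop("unknown mRNA class: ", mrna_class)
  if (!prot_class %in% colnames(lut)) stop("unknown protein class: ",
                                           prot_class)
  lut[mrna_class, prot_class]
}

#' Classify a gene's paired mRNA/protein response
#'
#' Deterministic rule table over the per-condition induction statuses and
#' the oscillation scores of the oscillatory-condition traces.
#'
#' mRNA (must be induced in at least one condition, else `NA`):
#' induced under both regimes and oscillation score above `osc_cutoff` with
#' at least one prominent interior extremum (non-monotonicity) gives
#' `osc_induced_both`;
#' induced under both
#' without oscillation gives `nonosc_induced_both`; induced under exactly
#' one regime gives `rising_only` / `osc_only`.
#'
#' Protein: not induced anywhere gives `not_induced`; induced under one
#' regime only gives `rising_only` / `osc_only`; induced under both is
#' `oscillatory` when the oscillation criterion holds, `rise_and_decrease`
#' when the oscillatory-condition z trace drops by more than `drop_z`
#' z-units below its peak by 9 h, and `rise_both` otherwise.
#'
#' @param status_mrna_osc,status_mrna_rise,status_prot_osc,status_prot_rise
#'   statuses from [select_de()] (`"induced"`, `"repressed"`,
#'   `"unchanged"`).
#' @param mrna_osc_score,prot_osc_score outputs of [oscillation_score()]
#'   for the oscillatory-condition replicate-mean traces.
#' @param prot_z_osc z-scored oscillatory-condition protein trace (0-9 h).
#' @param osc_cutoff oscillation-score cutoff (default 0.7).
#' @param drop_z late-decline z drop (default 1).
#' @return List with `mrna_class` and `prot_class` (either may be `NA`).
#' @export
classify_gene <- function(status_mrna_osc, status_mrna_rise,
                          status_prot_osc, status_prot_rise,
                          mrna_osc_score, prot_osc_score, prot_z_osc,
                          osc_cutoff = 0.7, drop_z = 1) {
  im_o <- status_mrna_osc == "induced"
  im_r <- status_mrna_rise == "induced"
  ip_o <- status_prot_osc == "induced"
  ip_r <- status_prot_rise == "induced"
  oscil <- function(s) s$score >= osc_cutoff && s$n_extrema >= 1
  mrna_class <- if (!im_o && !im_r) NA_character_
  else if (im_o && im_r) {
    if (oscil(mrna_osc_score)) "osc_induced_both" else "nonosc_induced_both"
  } else if (im_r) "rising_only" else "osc_only"
  prot_class <- if (!ip_o && !ip_r) "not_induced"
  else if (ip_o && ip_r) {
    if (oscil(prot_osc_score)) "oscillatory"
    else {
      pk <- which.max(prot_z_osc)
      if (prot_z_osc[length(prot_z_osc)] < prot_z_osc[pk] - drop_z)
        "rise_and_decrease"
      else "rise_both"
    }
  } else if (ip_r) "rising_only" else "osc_only"
  list(mrna_class = mrna_class, prot_class = prot_class)
}

#' Per-gene exclusive induction and cohort fractions
#'
#' A species is exclusively induced when it is induced under exactly one of
#' the two regimes. Cohort fractions follow the published denominators:
#' mRNAs among those induced in at least one condition; proteins among
#' those induced in at least one condition.
#'
#' @param status_osc,status_rise named status vectors (same genes).
#' @return List with `label` (per-gene: `"none"`, `"osc_only"`,
#'   `"rising_only"`, `"both"` given induction) and `fraction_exclusive`
#'   (among genes induced at least once).
#' @export
exclusive_induction <- function(status_osc, status_rise) {
  i_o <- status_osc == "induced"
  i_r <- status_rise == "induced"
  label <- ifelse(i_o & i_r, "both",
                  ifelse(i_o, "osc_only",
                         ifelse(i_r, "rising_only", "none")))
  eligible <- i_o | i_r
  frac <- if (any(eligible))
    sum(label %in% c("osc_only", "rising_only")) / sum(eligible)
  else NA_real_
  list(label = label, fraction_exclusive = frac)
}

#' Annotate the decoding mechanism implied by a category
#'
#' Rule-based annotation (evidence, not causal proof): categories a, b, e
#' arise from simple production-degradation regulation with distinct
#' degradation rates; i from a low transcriptional activation threshold;
#' c, f, g, k from the post-transcriptional activation-threshold family;
#' j from a transcriptional coherent FFL; d from a post-transcriptional
#' coherent FFL; h from an incoherent FFL. Anything else (including
#' `"unobserved*"`) is `undetermined`.
#'
#' @param letter category letter from [assign_category()].
#' @return Mechanism annotation string.
#' @export
infer_mechanism <- function(letter) {
  switch(letter,
         a = , b = , e = "simple_regulation",
         i = "activation_threshold_low",
         c = , f = , g = , k = "activation_threshold_posttranscriptional",
         j = "cffl_transcriptional",
         d = "cffl_posttranscriptional",
         h = "iffl",
         "undetermined")
}
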