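#' Between-condition area statistic (diff / diff_early)
#'
#' For basal-normalised protein trajectories under the two regimes, the
#' statistic sums, over the hourly grid points of the window, one minus the
#' ratio of the oscillatory to the rising normalised level:
#' `sum_t 1 - (osc(t)/osc(0)) / (rise(t)/rise(0))`.
#' The late window 3-9 h (inclusive at both ends, seven hourly points)
#' defines `diff`; the early window 0-3 h defines `diff_early`. The t = 3 h
#' point contributes to both windows, as the summation bounds are printed.
#'
#' @param prot_osc,prot_rise protein level vectors on a shared grid.
#' @param times matching times in hours.
#' @param window `"late"` (3-9 h), `"early"` (0-3 h), or a numeric
#'   `c(lo, hi)`.
#' @return The summed statistic (unitless).
#' @export
diff_score <- function(prot_osc, prot_rise, times, window = "late") {
  if (is.character(window))
    window <- switch(match.arg(window, c("late", "early")),
                     late = c(3, 9), early = c(0, 3))
  if (prot_osc[1] <= 0 || prot_rise[1] <= 0) stop("zero basal level")
  no <- prot_osc / prot_osc[1]
  nr <- prot_rise / prot_rise[1]
  idx <- which(times >= window[1] & times <= window[2])
  if (any(nr[idx] == 0)) stop("zero rising normalised level in window")
  sum(1 - no[idx] / nr[idx])
}

#' Order genes by their between-condition protein difference
#'
#' Stable descending sort by `diff`, ties broken by gene identifier, as used
#' to order the between-condition heatmap.
#'
#' @param diffs named numeric vector of per-gene `diff` values.
#' @return Character vector of gene ids in display order.
#' @export
rank_by_diff <- function(diffs) {
  names(diffs)[order(-diffs, names(diffs))]
}

#' Compare 24 h fold changes between functional classes
#'
#' Two-sample two-sided t-test of the per-gene protein fold changes at 24 h
#' between the anti-proliferative class and all other genes.
#'
#' @param fc24 named numeric vector of fold changes at 24 h.
#' @param annotation named character vector mapping genes to
#'   `"antiproliferative"` or `"other"`.
#' @return List with per-class `n` and `mean`, the `t` statistic, and the
#'   two-sided `p` value.
#' @export
class_comparison <- function(fc24, annotation) {
  cls <- annotation[names(fc24)]
  a <- fc24[cls == "antiproliferative"]
  b <- fc24[cls == "other"]
  if (length(a) < 2 || length(b) < 2)
    stop("each class needs at least two genes")
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b))
    return(list(n = c(antiproliferative = length(a), other = length(b)),
                mean = c(antiproliferative = mean(a), other = mean(b)),
                t = 0, p = 1))
  tt <- stats::t.test(a, b)
  list(n = c(antiproliferative = length(a), other = length(b)),
       mean = c(antiproliferative = mean(a), other = mean(b)),
       t = unname(tt$statistic), p = tt$p.value)
}
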