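#' Default observation grid
#'
#' The sampling design analysed throughout this package: hourly samples for
#' the first 9 hours after stimulation plus one late sample at 24 h.
#'
#' @return Numeric vector of sampling times in hours.
#' @export
default_grid <- function() c(0:9, 24)

#' Validate a time grid
#'
#' A valid grid is strictly increasing, non-negative, and contains t = 0
#' (the basal reference point for fold changes).
#'
#' @param times numeric vector of hours.
#' @return `times`, invisibly, after validation.
#' @export
validate_grid <- function(times) {
  if (length(times) == 0) stop("time grid is empty")
  if (any(!is.finite(times))) stop("time grid contains non-finite values")
  if (any(times < 0)) stop("time grid contains negative times")
  if (any(diff(times) <= 0)) stop("time grid must be strictly increasing")
  if (times[1] != 0) stop("time grid must contain t = 0")
  invisible(times)
}

#' Construct a time course
#'
#' A single species' relative abundance on a sampling grid for one condition
#' and replicate.
#'
#' @param species species identifier.
#' @param condition `"oscillatory"` or `"rising"`.
#' @param replicate integer replicate index (1-based).
#' @param times sampling times in hours (see [validate_grid()]).
#' @param levels non-negative relative levels, one per time point.
#' @return An object of class `time_course`.
#' @export
time_course <- function(species, condition, replicate, times, levels) {
  condition <- match.arg(condition, c("oscillatory", "rising"))
  validate_grid(times)
  if (length(levels) != length(times))
    stop("levels and times have different lengths")
  if (any(!is.finite(levels))) stop("levels contain non-finite values")
  if (any(levels < 0)) stop("levels must be non-negative")
  structure(
    list(species = species, condition = condition,
         replicate = as.integer(replicate),
         times = as.numeric(times), levels = as.numeric(levels)),
    class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("<time_course> %s | %s | rep %d | %d points (%g-%g h)\n",
              x$species, x$condition, x$replicate, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Linearly interpolate a trace onto an hourly grid
#'
#' The kinetic recursion runs on integer-hour steps; observed inputs sampled
#' on the sparser observation grid (0-9 h hourly, then 24 h) are linearly
#' interpolated across the unobserved 9-24 h gap and held constant beyond the
#' last sample.
#'
#' @param times observed times (hours).
#' @param levels observed levels.
#' @param t_max last hour of the internal grid (default `max(times)`).
#' @return Numeric vector of levels at `0:t_max`.
#' @export
interp_hourly <- function(times, levels, t_max = max(times)) {
  stats::approx(times, levels, xout = 0:t_max, rule = 2)$y
}
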