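#' Read a delimited expression time-course table
#'
#' Expected layout: header `gene_id,condition,replicate,<t0>,<t1>,...` with
#' time columns named by their hour (decimal allowed), conditions spelled
#' `"oscillatory"`/`"rising"`, 1-based replicate indices, comma or tab
#' delimited (auto-detected). All rows must share the grid implied by the
#' header; levels must be non-negative and complete (species with missing
#' values are not analysable and are rejected).
#'
#' @param path file path.
#' @param modality `"mRNA"` or `"protein"`; carried as an attribute.
#' @return A data frame of class `expression_table` (long-by-row, wide-by-
#'   time) with attributes `times` and `modality`.
#' @export
read_expression_table <- function(path, modality = c("mRNA", "protein")) {
  modality <- match.arg(modality)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("gene_id", "condition", "replicate")
  if (!all(required %in% names(df)))
    stop("missing required columns: ",
         paste(setdiff(required, names(df)), collapse = ", "))
  time_cols <- setdiff(names(df), required)
  times <- suppressWarnings(as.numeric(time_cols))
  if (any(is.na(times))) stop("non-numeric time column headers")
  o <- order(times)
  times <- times[o]
  time_cols <- time_cols[o]
  validate_grid(times)
  lv <- as.matrix(df[, time_cols, drop = FALSE])
  if (!is.numeric(lv)) stop("non-numeric expression levels")
  bad <- which(!stats::complete.cases(lv))
  if (length(bad))
    stop("missing values in rows: ", paste(utils::head(bad, 5), collapse = ", "))
  neg <- which(apply(lv, 1, function(r) any(r < 0)))
  if (length(neg))
    stop("negative levels in rows: ", paste(utils::head(neg, 5), collapse = ", "))
  if (!all(df$condition %in% c("oscillatory", "rising")))
    stop("conditions must be 'oscillatory' or 'rising'")
  key <- paste(df$gene_id, df$condition, df$replicate)
  if (anyDuplicated(key))
    stop("duplicate (gene_id, condition, replicate) keys")
  out <- cbind(df[required], as.data.frame(lv, check.names = FALSE))
  names(out) <- c(required, as.character(times))
  attr(out, "times") <- times
  attr(out, "modality") <- modality
  class(out) <- c("expression_table", "data.frame")
  out
}

#' Write an expression table deterministically
#'
#' Rows are sorted by (gene_id, condition, replicate) so that repeated runs
#' on the same data are byte-identical.
#'
#' @param table an `expression_table` (or compatible data frame).
#' @param path output path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(table, path, sep = ",") {
  o <- order(table$gene_id, table$condition, table$replicate)
  utils::write.table(table[o, , drop = FALSE], path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Extract the level matrix (replicates x times) of one gene/condition.
gene_levels <- function(table, gene, condition) {
  times <- attr(table, "times")
  rows <- table$gene_id == gene & table$condition == condition
  sub <- table[rows, , drop = FALSE]
  sub <- sub[order(sub$replicate), , drop = FALSE]
  m <- as.matrix(sub[, as.character(times), drop = FALSE])
  rownames(m) <- sub$replicate
  m
}

#' Fold change relative to basal expression
#'
#' Computed on the replicate-mean trace: `FC(t) = mean_level(t) /
#' mean_level(0)`. The basal level must be positive.
#'
#' @param levels numeric vector (one replicate) or matrix (replicates in
#'   rows) of levels, columns ordered by time with t = 0 first.
#' @return Numeric vector of fold changes; the first element is 1.
#' @export
fold_change <- function(levels) {
  m <- if (is.matrix(levels)) colMeans(levels) else as.numeric(levels)
  if (m[1] <= 0) stop("zero or negative basal level")
  m / m[1]
}

#' Maximum fold change inside a time window
#'
#' The headline induction statistic: the largest fold change attained at any
#' grid point inside the closed window, by default 1-9 h (the late 24 h
#' point is deliberately excluded).
#'
#' @param fc fold-change series (e.g. from [fold_change()]).
#' @param times matching times in hours.
#' @param window closed interval `c(lo, hi)` in hours.
#' @return The maximum fold change in the window.
#' @export
max_fold_change <- function(fc, times, window = c(1, 9)) {
  idx <- which(times >= window[1] & times <= window[2])
  if (length(idx) == 0) stop("no grid points inside the window")
  max(fc[idx])
}

#' z-score a trace over a window
#'
#' Centred and scaled (sample s.d.) over the grid points inside `window`,
#' by default 0-9 h: clustering operates on the first 9 hours and the 24 h
#' point is carried but not normalised against. Constant traces have no
#' defined z-score and return zeros with a warning.
#'
#' @param levels numeric levels.
#' @param times matching times in hours.
#' @param window closed interval over which to normalise.
#' @return Numeric z-scores at the in-window time points.
#' @export
zscore_trace <- function(levels, times, window = c(0, 9)) {
  idx <- which(times >= window[1] & times <= window[2])
  x <- levels[idx]
  s <- stats::sd(x)
  if (s == 0) {
    warning("constant trace: z-score undefined, returning zeros")
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Pearson correlation between two biological replicates
#'
#' @param rep1,rep2 level vectors on the same grid.
#' @return Pearson correlation coefficient.
#' @export
replicate_correlation <- function(rep1, rep2) {
  if (length(rep1) != length(rep2)) stop("replicates on different grids")
  if (stats::sd(rep1) == 0 || stats::sd(rep2) == 0)
    stop("zero variance in a replicate")
  stats::cor(rep1, rep2)
}
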