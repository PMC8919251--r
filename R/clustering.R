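#' Fuzzy c-means configuration
#'
#' Defaults follow the analysis this package implements: fuzzifier
#' `m = 1.3`, five clusters for mRNA and three for protein, Euclidean
#' distance on z-scored 0-9 h traces. Initialisation is seeded-random with
#' multiple restarts, keeping the solution with the lowest objective.
#'
#' @param n_clusters number of clusters (>= 2).
#' @param m fuzzifier exponent (> 1).
#' @param max_iter iteration cap per restart.
#' @param tol convergence tolerance on the objective.
#' @param seed RNG seed for initialisation.
#' @param restarts number of random restarts.
#' @return A list of class `cluster_config`.
#' @export
cluster_config <- function(n_clusters = 5, m = 1.3, max_iter = 200,
                           tol = 1e-9, seed = 1, restarts = 10) {
  if (n_clusters < 2) stop("n_clusters must be at least 2")
  if (m <= 1) stop("fuzzifier m must exceed 1")
  structure(list(n_clusters = as.integer(n_clusters), m = m,
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed), restarts = as.integer(restarts)),
            class = "cluster_config")
}

#' Fuzzy c-means clustering of z-scored time courses
#'
#' Wraps `e1071::cmeans` (standard fuzzy c-means with the Bezdek objective)
#' with seeded multi-restart initialisation. Memberships are row-stochastic;
#' the hard label is the argmax membership.
#'
#' @param z_matrix numeric matrix, genes in rows, z-scored time points in
#'   columns; row names are gene ids.
#' @param cfg a [cluster_config()].
#' @return List with `centers` (clusters x time), `membership` (genes x
#'   clusters), `cluster` (named hard labels), and `objective`.
#' @export
fuzzy_cmeans <- function(z_matrix, cfg = cluster_config()) {
  z_matrix <- as.matrix(z_matrix)
  if (any(!is.finite(z_matrix))) stop("non-finite entries in z matrix")
  if (nrow(z_matrix) < cfg$n_clusters)
    stop("fewer rows than clusters")
  best <- NULL
  for (r in seq_len(cfg$restarts)) {
    set.seed(cfg$seed + r - 1L)
    centers <- z_matrix[sample.int(nrow(z_matrix), cfg$n_clusters), ,
                        drop = FALSE] +
      matrix(stats::rnorm(cfg$n_clusters * ncol(z_matrix), sd = 1e-3),
             cfg$n_clusters)
    fit <- e1071::cmeans(z_matrix, centers = centers, m = cfg$m,
                         iter.max = cfg$max_iter, method = "cmeans")
    if (is.null(best) || fit$withinerror < best$withinerror) best <- fit
  }
  list(centers = best$centers,
       membership = best$membership,
       cluster = setNames(best$cluster, rownames(z_matrix)),
       objective = best$withinerror)
}

#' Label a cluster centre as induced or repressed
#'
#' A centre is induced when its mean z-score over 1-9 h exceeds its z-score
#' at t = 0 (an upward-shifted profile), repressed otherwise. Constant
#' centres are labelled `"unchanged"` with a warning.
#'
#' @param center numeric centre profile.
#' @param times matching times in hours.
#' @return `"induced"`, `"repressed"`, or `"unchanged"`.
#' @export
label_direction <- function(center, times) {
  if (stats::sd(center) == 0) {
    warning("constant cluster centre")
    return("unchanged")
  }
  z0 <- center[which(times == 0)]
  later <- mean(center[times >= 1 & times <= 9])
  if (later > z0) "induced" else "repressed"
}

#' Cluster one modality's induced-gene traces and label directions
#'
#' Convenience wrapper: z-scores each gene's replicate-mean trace over
#' 0-9 h, runs [fuzzy_cmeans()], and labels each cluster's direction.
#'
#' @param table an `expression_table`.
#' @param condition condition to cluster.
#' @param genes genes to include (default all in the table).
#' @param cfg a [cluster_config()].
#' @return Data frame with `gene_id`, `cluster`, `membership_max`,
#'   `direction`, plus attributes `centers` and `directions`.
#' @export
cluster_timecourses <- function(table, condition, genes = NULL,
                                cfg = cluster_config()) {
  times <- attr(table, "times")
  if (is.null(genes)) genes <- sort(unique(table$gene_id))
  win <- times[times >= 0 & times <= 9]
  z <- t(vapply(genes, function(g) {
    zscore_trace(fold_change(gene_levels(table, g, condition)), times)
  }, numeric(length(win))))
  rownames(z) <- genes
  keep <- apply(z, 1, function(r) any(r != 0))
  z <- z[keep, , drop = FALSE]
  fit <- fuzzy_cmeans(z, cfg)
  directions <- apply(fit$centers, 1, label_direction, times = win)
  out <- data.frame(gene_id = rownames(z),
                    condition = condition,
                    cluster = unname(fit$cluster),
                    membership_max = apply(fit$membership, 1, max),
                    direction = unname(directions[fit$cluster]),
                    stringsAsFactors = FALSE)
  attr(out, "centers") <- fit$centers
  attr(out, "directions") <- directions
  attr(out, "times") <- win
  out
}

#' Genes belonging to induced-direction clusters
#'
#' @param assignments output of [cluster_timecourses()].
#' @return Sorted character vector of gene ids whose hard-label cluster is
#'   induced.
#' @export
select_induced_clusters <- function(assignments) {
  sort(assignments$gene_id[assignments$direction == "induced"])
}
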