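#' Differential-expression criteria
#'
#' Selection thresholds for calling a species induced: maximum fold change
#' (1-9 h) above `fc_threshold`, Benjamini-Hochberg adjusted p-value below
#' `fdr_threshold` at one or more time points, replicate Pearson correlation
#' above `pcc_threshold`, and (proteins only) the early between-condition
#' area statistic `diff_early` below `diff_early_max`.
#'
#' Two published protein presets exist and disagree; both are exposed.
#' `"methods"` (the default) uses FDR < 0.05 and PCC > 0.7; `"relaxed"` uses
#' the figure-legend pairing FDR < 0.2 and PCC > 0.5. mRNA thresholds are
#' FC > 1.5, FDR < 0.2, PCC > 0.5 in both presets.
#'
#' @param modality `"mRNA"` or `"protein"`.
#' @param preset `"methods"` or `"relaxed"` (protein thresholds only).
#' @param fc_threshold,fdr_threshold,pcc_threshold,diff_early_max overrides.
#' @return A list of class `de_criteria`.
#' @export
de_criteria <- function(modality = c("mRNA", "protein"),
                        preset = c("methods", "relaxed"),
                        fc_threshold = NULL, fdr_threshold = NULL,
                        pcc_threshold = NULL, diff_early_max = NULL) {
  modality <- match.arg(modality)
  preset <- match.arg(preset)
  if (modality == "mRNA") {
    defaults <- list(fc_threshold = 1.5, fdr_threshold = 0.2,
                     pcc_threshold = 0.5, diff_early_max = Inf)
  } else if (preset == "methods") {
    defaults <- list(fc_threshold = 1.15, fdr_threshold = 0.05,
                     pcc_threshold = 0.7, diff_early_max = 1)
  } else {
    defaults <- list(fc_threshold = 1.15, fdr_threshold = 0.2,
                     pcc_threshold = 0.5, diff_early_max = 1)
  }
  out <- list(modality = modality,
              fc_threshold = fc_threshold %||% defaults$fc_threshold,
              fdr_threshold = fdr_threshold %||% defaults$fdr_threshold,
              pcc_threshold = pcc_threshold %||% defaults$pcc_threshold,
              diff_early_max = diff_early_max %||% defaults$diff_early_max)
  if (out$fc_threshold <= 1) stop("fc_threshold must exceed 1")
  structure(out, class = "de_criteria")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-sample t-test of one time point against basal
#'
#' Two-sided Student t-test (pooled variance) comparing the replicate levels
#' at time t with the replicate levels at t = 0. With only two replicates
#' per group the test is underpowered. Groups with zero pooled variance do
#' not error: equal means give p = 1 and unequal means give p = 0, the
#' noise-free limits of the test, so that noiseless synthetic data remain
#' analysable end to end.
#'
#' @param x_t replicate levels at time t.
#' @param x_0 replicate levels at t = 0.
#' @return Two-sided p-value.
#' @export
ttest_vs_basal <- function(x_t, x_0) {
  if (length(x_t) < 2 || length(x_0) < 2)
    stop("need at least two replicates per group")
  if (stats::sd(x_t) == 0 && stats::sd(x_0) == 0)
    return(if (isTRUE(all.equal(mean(x_t), mean(x_0)))) 1 else 0)
  stats::t.test(x_t, x_0, var.equal = TRUE)$p.value
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return Adjusted q-values, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify every gene in one condition as induced, repressed, or unchanged
#'
#' For each gene the per-time-point basal-contrast t-tests are computed,
#' BH-adjusted (by default across all gene x time tests of the call, i.e.
#' one family per modality and condition; set `family = "per_timepoint"` for
#' per-time-point families), and combined with the maximum fold change over
#' 1-9 h and the replicate correlation:
#' induced requires max FC > `fc_threshold`, min q < `fdr_threshold`,
#' PCC > `pcc_threshold`, and (proteins) `diff_early` < `diff_early_max`;
#' repressed mirrors the FC criterion (min FC < 1 / `fc_threshold`);
#' everything else is unchanged.
#'
#' @param table an `expression_table`.
#' @param condition `"oscillatory"` or `"rising"`.
#' @param criteria a [de_criteria()].
#' @param diff_early optional named vector of per-gene `diff_early` values
#'   (proteins; computed with [diff_score()] between the two conditions).
#' @param family `"global"` or `"per_timepoint"` BH family.
#' @return Data frame of class `de_result`: one row per gene with `max_fc`,
#'   `min_fc`, `min_q`, `pcc`, `diff_early`, `status`, `detected`.
#' @export
select_de <- function(table, condition, criteria, diff_early = NULL,
                      family = c("global", "per_timepoint")) {
  family <- match.arg(family)
  times <- attr(table, "times")
  genes <- sort(unique(table$gene_id))
  if (length(genes) == 0) stop("empty expression table")
  later <- which(times > 0)
  pmat <- matrix(NA_real_, length(genes), length(later),
                 dimnames = list(genes, times[later]))
  max_fc <- min_fc <- pcc <- setNames(numeric(length(genes)), genes)
  for (g in genes) {
    lv <- gene_levels(table, g, condition)
    fc <- fold_change(lv)
    max_fc[g] <- max_fold_change(fc, times)
    min_fc[g] <- min(fc[times >= 1 & times <= 9])
    pcc[g] <- if (nrow(lv) >= 2 &&
                  stats::sd(lv[1, ]) > 0 && stats::sd(lv[2, ]) > 0)
      stats::cor(lv[1, ], lv[2, ]) else 0
    pmat[g, ] <- vapply(later, function(j) ttest_vs_basal(lv[, j], lv[, 1]),
                        numeric(1))
  }
  qmat <- if (family == "global") {
    matrix(bh_adjust(as.vector(pmat)), nrow(pmat), ncol(pmat),
           dimnames = dimnames(pmat))
  } else apply(pmat, 2, bh_adjust)
  min_q <- apply(qmat, 1, min)
  de <- if (is.null(diff_early)) rep(NA_real_, length(genes))
        else unname(diff_early[genes])
  de_ok <- is.na(de) | de < criteria$diff_early_max
  induced <- max_fc > criteria$fc_threshold & min_q < criteria$fdr_threshold &
    pcc > criteria$pcc_threshold & de_ok
  repressed <- !induced & min_fc < 1 / criteria$fc_threshold &
    min_q < criteria$fdr_threshold & pcc > criteria$pcc_threshold
  status <- ifelse(induced, "induced", ifelse(repressed, "repressed",
                                              "unchanged"))
  out <- data.frame(gene_id = genes, condition = condition,
                    modality = criteria$modality,
                    max_fc = unname(max_fc), min_fc = unname(min_fc),
                    min_q = unname(min_q), pcc = unname(pcc),
                    diff_early = de, status = status, detected = TRUE,
                    stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Genes called induced in a DE result
#'
#' @param de a `de_result` from [select_de()].
#' @return Character vector of induced gene ids (sorted).
#' @export
induced_genes <- function(de) sort(de$gene_id[de$status == "induced"])
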