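#' Pipeline configuration
#'
#' Gathers every stage's settings with the package defaults: DE criteria per
#' modality, cluster configurations (five mRNA clusters, three protein
#' clusters, fuzzifier 1.3), fitting options, classification cutoffs, and
#' the synthetic-cohort settings when no input tables are supplied.
#'
#' @param n_genes synthetic cohort size.
#' @param mechanism_mix mechanism proportions (see [gen_cohort()]).
#' @param cv replicate noise coefficient of variation.
#' @param seed master seed.
#' @param de_mrna,de_protein [de_criteria()] per modality.
#' @param cluster_mrna,cluster_protein [cluster_config()] per modality.
#' @param tdel_max,fit_window fitting options (see [fit_protein()]).
#' @param osc_cutoff,drop_z classification cutoffs (see [classify_gene()]).
#' @param outdir output directory (`NULL` to skip writing).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_genes = 200,
                            mechanism_mix = c(simple = 0.5,
                                              threshold = 0.15,
                                              cffl_transcriptional = 0.1,
                                              cffl_posttranscriptional = 0.1,
                                              iffl = 0.15),
                            cv = 0.05, seed = 1,
                            de_mrna = de_criteria("mRNA"),
                            de_protein = de_criteria("protein"),
                            cluster_mrna = cluster_config(5),
                            cluster_protein = cluster_config(3),
                            tdel_max = 3, fit_window = c(0, 9),
                            osc_cutoff = 0.7, drop_z = 1,
                            outdir = NULL) {
  if (n_genes <= 0) stop("n_genes must be positive")
  structure(list(n_genes = n_genes, mechanism_mix = mechanism_mix, cv = cv,
                 seed = seed, de_mrna = de_mrna, de_protein = de_protein,
                 cluster_mrna = cluster_mrna,
                 cluster_protein = cluster_protein, tdel_max = tdel_max,
                 fit_window = fit_window, osc_cutoff = osc_cutoff,
                 drop_z = drop_z, outdir = outdir),
            class = "pipeline_config")
}

# replicate-mean trace of one gene/condition
mean_trace <- function(table, gene, condition) {
  colMeans(gene_levels(table, gene, condition))
}

#' Differential expression for both modalities and conditions of a cohort
#'
#' Computes the protein `diff_early` filter (early between-condition area on
#' replicate-mean fold-change traces) before applying the protein criteria.
#'
#' @param mrna_table,prot_table `expression_table`s.
#' @param de_mrna,de_protein [de_criteria()].
#' @return Named list of `de_result`s: `mrna_osc`, `mrna_rise`, `prot_osc`,
#'   `prot_rise`, plus `diff_early` (named vector).
#' @export
run_de <- function(mrna_table, prot_table,
                   de_mrna = de_criteria("mRNA"),
                   de_protein = de_criteria("protein")) {
  times <- attr(prot_table, "times")
  genes <- sort(unique(prot_table$gene_id))
  de_early <- setNames(vapply(genes, function(g) {
    diff_score(mean_trace(prot_table, g, "oscillatory"),
               mean_trace(prot_table, g, "rising"), times, "early")
  }, numeric(1)), genes)
  list(mrna_osc = select_de(mrna_table, "oscillatory", de_mrna),
       mrna_rise = select_de(mrna_table, "rising", de_mrna),
       prot_osc = select_de(prot_table, "oscillatory", de_protein,
                            diff_early = de_early),
       prot_rise = select_de(prot_table, "rising", de_protein,
                             diff_early = de_early),
       diff_early = de_early)
}

#' Classify every gene of a cohort into the dynamical category table
#'
#' Combines per-condition DE statuses, oscillation scores against the
#' oscillatory p53 reference, and the category lookup, and annotates the
#' implied decoding mechanism.
#'
#' @param mrna_table,prot_table `expression_table`s.
#' @param de output of [run_de()].
#' @param p53_osc oscillatory p53 reference [time_course()].
#' @param osc_cutoff,drop_z see [classify_gene()].
#' @return Data frame: gene_id, classes, letter, mechanism, scores.
#' @export
classify_cohort <- function(mrna_table, prot_table, de, p53_osc,
                            osc_cutoff = 0.7, drop_z = 1) {
  times <- attr(mrna_table, "times")
  genes <- sort(unique(mrna_table$gene_id))
  status <- function(res, g) res$status[match(g, res$gene_id)]
  out <- lapply(genes, function(g) {
    m_tr <- mean_trace(mrna_table, g, "oscillatory")
    p_tr <- mean_trace(prot_table, g, "oscillatory")
    ms <- oscillation_score(times, m_tr, p53_osc$times, p53_osc$levels)
    ps <- oscillation_score(times, p_tr, p53_osc$times, p53_osc$levels)
    suppressWarnings(pz <- zscore_trace(p_tr, times))
    cls <- classify_gene(status(de$mrna_osc, g), status(de$mrna_rise, g),
                         status(de$prot_osc, g), status(de$prot_rise, g),
                         ms, ps, pz, osc_cutoff, drop_z)
    letter <- if (is.na(cls$mrna_class)) NA_character_
    else assign_category(cls$mrna_class, cls$prot_class)
    data.frame(gene_id = g, mrna_class = cls$mrna_class %||% NA_character_,
               prot_class = cls$prot_class,
               letter = letter,
               mechanism = if (is.na(letter)) NA_character_
               else infer_mechanism(letter),
               mrna_osc_score = ms$score, prot_osc_score = ps$score,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fit and cross-predict every analysable gene of a cohort
#'
#' For each requested gene: fit mRNA rates against the oscillatory p53
#' input, fit protein rates against the oscillatory mRNA input, then freeze
#' the protein parameters and predict the rising-condition protein from the
#' rising mRNA input, reporting all goodness-of-fit values.
#'
#' @param mrna_table,prot_table `expression_table`s.
#' @param p53_osc oscillatory p53 input [time_course()].
#' @param genes genes to fit (default all).
#' @param tdel_max,window see [fit_protein()].
#' @return Data frame: gene_id, kp/kd/tdel estimates, r2_mrna, r2_prot,
#'   r2_pred.
#' @export
fit_cohort <- function(mrna_table, prot_table, p53_osc, genes = NULL,
                       tdel_max = 3, window = c(0, 9)) {
  times <- attr(mrna_table, "times")
  if (is.null(genes)) genes <- sort(unique(mrna_table$gene_id))
  out <- lapply(genes, function(g) {
    m_osc <- mean_trace(mrna_table, g, "oscillatory")
    p_osc <- mean_trace(prot_table, g, "oscillatory")
    m_rise <- mean_trace(mrna_table, g, "rising")
    p_rise <- mean_trace(prot_table, g, "rising")
    fm <- fit_mrna(p53_osc$times, p53_osc$levels, times, m_osc,
                   window = window)
    fp <- fit_protein(times, m_osc, times, p_osc, tdel_max = tdel_max,
                      window = window)
    pr <- predict_cross_condition(fp, times, m_rise, times, p_rise,
                                  window = window)
    data.frame(gene_id = g, kp_mrna = fm$kp, kd_mrna = fm$kd,
               kp_prot = fp$kp, kd_prot = fp$kd, tdel = fp$tdel,
               r2_mrna = fm$r2, r2_prot = fp$r2, r2_pred = pr$r2,
               flagged_mrna = fm$flagged, flagged_prot = fp$flagged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: synthesise the cohort; differential-expression
#' filtering per modality and condition; fuzzy c-means clustering of
#' induced mRNAs (and of their cognate proteins); kinetic fitting under the
#' oscillatory regime and cross-condition prediction; dynamical-category
#' classification and exclusive-induction summary; between-condition diff
#' statistics and the functional-class comparison. When `config$outdir` is
#' set, every stage writes a delimited table plus a run manifest; reruns
#' with the same configuration are identical.
#'
#' @param config a [pipeline_config()].
#' @return List with all stage outputs (`cohort`, `de`, `clusters`, `fits`,
#'   `categories`, `exclusivity`, `diffs`, `class_comparison`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- gen_cohort(config$n_genes, config$mechanism_mix,
                       noise_model(config$cv), seed = config$seed)
  mrna <- cohort_table(cohort, "mRNA")
  prot <- cohort_table(cohort, "protein")
  de <- run_de(mrna, prot, config$de_mrna, config$de_protein)

  ind_osc <- induced_genes(de$mrna_osc)
  ind_rise <- induced_genes(de$mrna_rise)
  clusters <- list()
  if (length(ind_osc) >= config$cluster_mrna$n_clusters)
    clusters$mrna_osc <- cluster_timecourses(mrna, "oscillatory", ind_osc,
                                             config$cluster_mrna)
  if (length(ind_rise) >= config$cluster_mrna$n_clusters)
    clusters$mrna_rise <- cluster_timecourses(mrna, "rising", ind_rise,
                                              config$cluster_mrna)
  prot_of_induced <- intersect(union(ind_osc, ind_rise),
                               unique(prot$gene_id))
  if (length(prot_of_induced) >= config$cluster_protein$n_clusters)
    clusters$prot_osc <- cluster_timecourses(prot, "oscillatory",
                                             prot_of_induced,
                                             config$cluster_protein)

  fit_genes <- intersect(ind_osc, induced_genes(de$prot_osc))
  fits <- if (length(fit_genes))
    fit_cohort(mrna, prot, cohort$p53_osc, fit_genes,
               tdel_max = config$tdel_max, window = config$fit_window)
  else NULL

  categories <- classify_cohort(mrna, prot, de, cohort$p53_osc,
                                config$osc_cutoff, config$drop_z)
  excl_mrna <- exclusive_induction(
    setNames(de$mrna_osc$status, de$mrna_osc$gene_id),
    setNames(de$mrna_rise$status, de$mrna_rise$gene_id))
  excl_prot <- exclusive_induction(
    setNames(de$prot_osc$status, de$prot_osc$gene_id),
    setNames(de$prot_rise$status, de$prot_rise$gene_id))

  times <- attr(prot, "times")
  genes <- sort(unique(prot$gene_id))
  diffs <- setNames(vapply(genes, function(g) {
    diff_score(mean_trace(prot, g, "oscillatory"),
               mean_trace(prot, g, "rising"), times, "late")
  }, numeric(1)), genes)
  fc24 <- setNames(vapply(genes, function(g) {
    fc <- fold_change(gene_levels(prot, g, "rising"))
    fc[length(fc)]
  }, numeric(1)), genes)
  cc <- class_comparison(fc24, cohort$annotation)

  result <- list(cohort = cohort, de = de, clusters = clusters,
                 fits = fits, categories = categories,
                 exclusivity = list(mrna = excl_mrna, prot = excl_prot),
                 diffs = diffs, diff_order = rank_by_diff(diffs),
                 class_comparison = cc)
  result$manifest <- pipeline_manifest(config, result)
  if (!is.null(config$outdir)) write_pipeline(result, config)
  result
}

pipeline_manifest <- function(config, result) {
  list(seed = config$seed, n_genes = config$n_genes, cv = config$cv,
       n_induced_mrna_osc = length(induced_genes(result$de$mrna_osc)),
       n_induced_mrna_rise = length(induced_genes(result$de$mrna_rise)),
       n_induced_prot_osc = length(induced_genes(result$de$prot_osc)),
       n_induced_prot_rise = length(induced_genes(result$de$prot_rise)),
       frac_exclusive_mrna = result$exclusivity$mrna$fraction_exclusive,
       frac_exclusive_prot = result$exclusivity$prot$fraction_exclusive)
}

write_pipeline <- function(result, config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.table(df, file.path(config$outdir, name), sep = ",",
                       quote = FALSE, row.names = FALSE)
  write_expression_table(cohort_table(result$cohort, "mRNA"),
                         file.path(config$outdir, "mrna_table.csv"))
  write_expression_table(cohort_table(result$cohort, "protein"),
                         file.path(config$outdir, "protein_table.csv"))
  w(cohort_truth(result$cohort), "truth.csv")
  for (nm in names(result$de))
    if (is.data.frame(result$de[[nm]]))
      w(result$de[[nm]], paste0("de_", nm, ".csv"))
  for (nm in names(result$clusters))
    w(result$clusters[[nm]], paste0("clusters_", nm, ".csv"))
  if (!is.null(result$fits)) w(result$fits, "fits.csv")
  w(result$categories, "categories.csv")
  w(data.frame(gene_id = names(result$diffs),
               diff = unname(result$diffs)), "diffs.csv")
  manifest <- result$manifest
  writeLines(paste(names(manifest), unlist(manifest), sep = "="),
             file.path(config$outdir, "manifest.txt"))
  invisible(config$outdir)
}
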