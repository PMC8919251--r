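#' Specify a gene's decoding mechanism for the synthetic generator
#'
#' Five generating mechanisms are supported: `"simple"` (plain
#' production-degradation kinetics), `"threshold"` (activation threshold,
#' translational by default), `"cffl_transcriptional"`,
#' `"cffl_posttranscriptional"` (coherent feed-forward persistence
#' detectors), and `"iffl"` (incoherent feed-forward repression). Threshold
#' levels may be given numerically or symbolically (`"medium"`/`"high"`),
#' in which case they are calibrated against the gene's own noiseless
#' input range at simulation time: medium is the geometric midpoint of the
#' maximum input under the two regimes (crossed only under rising), high is
#' twice the rising maximum (never crossed).
#'
#' @param mechanism one of the five mechanisms.
#' @param kinetics a [kinetic_params()].
#' @param theta threshold level: numeric, `"medium"`, or `"high"`
#'   (threshold mechanism only).
#' @param threshold_level `"translational"` or `"transcriptional"`.
#' @param ffl an [ffl_spec()] (FFL mechanisms only); its `y_threshold` may
#'   be `NA` for self-calibration.
#' @return A list of class `mechanism_spec`.
#' @export
mechanism_spec <- function(mechanism = c("simple", "threshold",
                                         "cffl_transcriptional",
                                         "cffl_posttranscriptional", "iffl"),
                           kinetics = kinetic_params(),
                           theta = "medium",
                           threshold_level = "translational",
                           ffl = NULL) {
  mechanism <- match.arg(mechanism)
  if (mechanism %in% c("cffl_transcriptional", "cffl_posttranscriptional",
                       "iffl") && is.null(ffl))
    ffl <- default_ffl(mechanism)
  structure(list(mechanism = mechanism, kinetics = kinetics, theta = theta,
                 threshold_level = threshold_level, ffl = ffl),
            class = "mechanism_spec")
}

# Default intermediate (Y) kinetics per FFL mechanism. Coherent loops use a
# slow, delayed Y (a persistence integrator); the incoherent loop uses a
# fast Y that tracks the input, closing the repression gate whenever p53 is
# high and re-opening it in the troughs between pulses.
default_ffl <- function(mechanism) {
  switch(mechanism,
         cffl_transcriptional = ffl_spec("coherent", "transcriptional",
                                         y_production = 0.1,
                                         y_degradation = 0.1,
                                         y_delay = 1, y_threshold = NA,
                                         y_hill_n = 16),
         cffl_posttranscriptional = ffl_spec("coherent",
                                             "posttranscriptional",
                                             y_production = 0.1,
                                             y_degradation = 0.1,
                                             y_delay = 1, y_threshold = NA,
                                             y_hill_n = 16),
         iffl = ffl_spec("incoherent", "posttranscriptional",
                         y_production = 0.3, y_degradation = 0.4,
                         y_delay = 1, y_threshold = NA, y_hill_n = 16,
                         repression = 19))
}

#' Measurement noise model
#'
#' Multiplicative log-normal noise, independent across replicates and
#' observations: each sampled level is multiplied by
#' `exp(rnorm(1, 0, sdlog))` with `sdlog = sqrt(log(1 + cv^2))`, keeping
#' levels positive and giving the stated coefficient of variation.
#'
#' @param cv coefficient of variation (>= 0).
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(cv = 0.1) {
  if (cv < 0) stop("cv must be non-negative")
  structure(list(cv = cv, sdlog = sqrt(log1p(cv^2))), class = "noise_model")
}

#' Noiseless mechanism simulation under both p53 regimes
#'
#' Runs one mechanism's kinetics on hourly p53 inputs for both regimes and
#' returns the noiseless truth traces. Symbolic (self-calibrated)
#' thresholds are resolved here, which is why both regimes' inputs are
#' required even to simulate one of them.
#'
#' @param mech a [mechanism_spec()].
#' @param p53_osc_h,p53_rise_h p53 levels on a shared hourly grid from 0 h.
#' @return List with `oscillatory` and `rising` (each `mrna` + `protein`
#'   traces, FFLs also `y`), plus any resolved `theta` / `y_threshold`.
#' @export
simulate_mechanism <- function(mech, p53_osc_h, p53_rise_h) {
  k <- mech$kinetics
  run_simple <- function(x) {
    m <- simulate_mrna(x, k$kp_mrna, k$kd_mrna)
    list(mrna = m, protein = simulate_protein(m, k$kp_prot, k$kd_prot,
                                              k$tdel))
  }
  if (mech$mechanism == "simple") {
    return(list(oscillatory = run_simple(p53_osc_h),
                rising = run_simple(p53_rise_h)))
  }
  if (mech$mechanism == "threshold") {
    theta <- mech$theta
    if (is.character(theta)) {
      if (mech$threshold_level == "translational") {
        mo <- simulate_mrna(p53_osc_h, k$kp_mrna, k$kd_mrna)
        mr <- simulate_mrna(p53_rise_h, k$kp_mrna, k$kd_mrna)
        lo <- max(mo)
        hi <- max(mr)
      } else {
        lo <- max(p53_osc_h)
        hi <- max(p53_rise_h)
      }
      theta <- switch(theta, medium = sqrt(lo * hi), high = 2 * hi,
                      stop("theta must be numeric, 'medium', or 'high'"))
    }
    spec <- threshold_spec(theta, level = mech$threshold_level)
    return(list(oscillatory = simulate_threshold(p53_osc_h, spec, k),
                rising = simulate_threshold(p53_rise_h, spec, k),
                theta = theta))
  }
  ffl <- mech$ffl
  if (is.na(ffl$y_threshold)) {
    # Self-calibration against the two regimes' intermediate trajectories.
    # Incoherent loop: gate well above the oscillatory Y maximum, so pulses
    # never engage the repressor but a sustained input soon does.
    # Coherent transcriptional loop: gate midway (geometric) between the
    # oscillatory maximum and the rising 9 h level, leaving time for the
    # downstream mRNA-then-protein response within the sampled window.
    # Coherent post-transcriptional loop: gate just below the rising 9 h
    # level - translation responds immediately, so persistence detection
    # can run to the edge of the window.
    yo <- simulate_y(p53_osc_h, ffl)
    yr <- simulate_y(p53_rise_h, ffl)
    w <- seq_len(min(10, length(yo)))           # 0-9 h
    yr9 <- yr[min(10, length(yr))]
    ffl$y_threshold <-
      if (mech$mechanism == "iffl") 1.35 * max(yo[w])
      else if (ffl$level == "transcriptional") sqrt(max(yo[w]) * yr9)
      else 0.95 * yr9
  }
  sim <- if (mech$mechanism == "iffl")
    function(x) simulate_iffl(x, ffl, k)
  else function(x) simulate_cffl(x, ffl, k)
  list(oscillatory = sim(p53_osc_h), rising = sim(p53_rise_h),
       y_threshold = ffl$y_threshold)
}

#' Simulate one gene's mRNA and protein under both p53 regimes
#'
#' Produces a gene record: noiseless hourly truth plus noisy observations
#' for both modalities, both conditions, and all replicates on the
#' observation grid.
#'
#' @param mech a [mechanism_spec()].
#' @param p53_osc,p53_rise p53 inputs as [time_course()] objects, ideally on
#'   an hourly grid (sparser grids are linearly interpolated).
#' @param noise a [noise_model()].
#' @param n_replicates number of replicates per condition (default 2).
#' @param times observation grid (default [default_grid()]).
#' @param gene_id identifier.
#' @return A list of class `gene_record`: `gene_id`, `mechanism`, `spec`,
#'   `truth` (noiseless hourly traces per condition), and `data` (long data
#'   frame: modality, condition, replicate, time, level).
#' @export
simulate_gene <- function(mech, p53_osc, p53_rise, noise = noise_model(0),
                          n_replicates = 2, times = default_grid(),
                          gene_id = "gene") {
  stopifnot(inherits(mech, "mechanism_spec"))
  if (!identical(p53_osc$times, p53_rise$times))
    stop("p53 inputs must share one grid")
  t_max <- max(times)
  osc_h <- interp_hourly(p53_osc$times, p53_osc$levels, t_max)
  rise_h <- interp_hourly(p53_rise$times, p53_rise$levels, t_max)
  truth <- simulate_mechanism(mech, osc_h, rise_h)
  idx <- match(round(times), 0:t_max)
  rows <- list()
  for (cond in c("oscillatory", "rising")) {
    for (mod in c("mRNA", "protein")) {
      base <- truth[[cond]][[if (mod == "mRNA") "mrna" else "protein"]][idx]
      for (r in seq_len(n_replicates)) {
        lv <- base * exp(stats::rnorm(length(base), 0, noise$sdlog))
        rows[[length(rows) + 1L]] <-
          data.frame(gene_id = gene_id, modality = mod, condition = cond,
                     replicate = r, time = times, level = lv,
                     stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(gene_id = gene_id, mechanism = mech$mechanism, spec = mech,
                 truth = truth, times = times,
                 data = do.call(rbind, rows)),
            class = "gene_record")
}

#' Parameter ranges used when drawing cohort genes
#'
#' Documented sampling ranges per mechanism. Simple-regulation genes draw
#' fast mRNA turnover (their mRNA follows the pulsed input) and a protein
#' degradation fraction from one of two stability bands - labile proteins
#' that track their mRNA and stable proteins that integrate it - mirroring
#' the separation of degradation rates between oscillatory and rising
#' protein clusters. Medium-threshold genes draw slow mRNA turnover (a
#' smooth, non-oscillatory mRNA response); high-threshold genes draw fast
#' mRNA turnover. FFL genes use fast mRNA turnover so their mRNA mirrors
#' the p53 input, and the incoherent loop pairs a stable protein with a
#' long translational delay so repression under a sustained input can
#' pre-empt induction. Production rates only set scale.
#'
#' @return Nested list of ranges (two-column matrices are stability bands,
#'   one row drawn uniformly).
#' @export
cohort_ranges <- function() {
  list(simple = list(kd_mrna = c(0.5, 0.9),
                     kd_prot = rbind(c(0.05, 0.25), c(0.65, 0.95)),
                     kp = c(0.5, 2), tdel = c(0, 1)),
       threshold_medium = list(kd_mrna = c(0.12, 0.2),
                               kd_prot = c(0.2, 0.5),
                               kp = c(0.5, 2), tdel = c(0.25, 1)),
       threshold_high = list(kd_mrna = c(0.5, 0.9), kd_prot = c(0.1, 0.5),
                             kp = c(0.5, 2), tdel = c(0.25, 1)),
       cffl_transcriptional = list(kd_mrna = c(0.3, 0.7),
                                   kd_prot = c(0.3, 0.7), kp = c(0.5, 2),
                                   tdel = c(0.25, 1)),
       cffl_posttranscriptional = list(kd_mrna = c(0.5, 0.9),
                                       kd_prot = c(0.15, 0.35),
                                       kp = c(0.5, 2), tdel = c(0.25, 1)),
       iffl = list(kd_mrna = c(0.5, 0.9), kd_prot = c(0.04, 0.08),
                   kp = c(0.5, 2), tdel = c(2, 3)))
}

#' Draw one gene's mechanism specification from the documented ranges
#'
#' Samples kinetic parameters (and, for thresholds, the threshold level)
#' from [cohort_ranges()] using the current RNG state.
#'
#' @param mechanism one of the five generator mechanisms.
#' @param ranges range list, defaulting to [cohort_ranges()].
#' @return A [mechanism_spec()].
#' @export
draw_mechanism <- function(mechanism, ranges = cohort_ranges()) {
  theta <- NULL
  key <- mechanism
  if (mechanism == "threshold") {
    theta <- sample(c("medium", "high"), 1)
    key <- paste0("threshold_", theta)
  }
  r <- ranges[[key]]
  u <- function(rg) {
    if (is.matrix(rg)) rg <- rg[sample.int(nrow(rg), 1), ]
    stats::runif(1, rg[1], rg[2])
  }
  kin <- kinetic_params(kp_mrna = u(r$kp), kd_mrna = u(r$kd_mrna),
                        kp_prot = u(r$kp), kd_prot = u(r$kd_prot),
                        tdel = sample(seq(r$tdel[1], r$tdel[2],
                                          by = 0.25), 1))
  if (mechanism == "threshold")
    mechanism_spec("threshold", kin, theta = theta)
  else mechanism_spec(mechanism, kin)
}

#' Generate a mechanism-labelled synthetic cohort
#'
#' Draws `n_genes` genes with mechanisms sampled from `mechanism_mix`,
#' kinetic parameters from [cohort_ranges()], and replicate noise from
#' `noise`. Fully deterministic given `seed`. A quarter of genes are
#' randomly tagged `"antiproliferative"` to exercise the functional-class
#' comparison.
#'
#' @param n_genes number of genes (> 0).
#' @param mechanism_mix named proportions over mechanisms, summing to 1.
#' @param noise a [noise_model()].
#' @param seed RNG seed.
#' @param n_replicates replicates per condition.
#' @param times observation grid.
#' @param p53_osc_spec,p53_rise_spec waveform specs for the two regimes.
#' @return A list of class `cohort`: `genes` (list of `gene_record`),
#'   `p53_osc`, `p53_rise` (hourly input time courses), `annotation`
#'   (named functional-class vector), `seed`.
#' @export
gen_cohort <- function(n_genes,
                       mechanism_mix = c(simple = 0.5, threshold = 0.15,
                                         cffl_transcriptional = 0.1,
                                         cffl_posttranscriptional = 0.1,
                                         iffl = 0.15),
                       noise = noise_model(0.1), seed = 1,
                       n_replicates = 2, times = default_grid(),
                       p53_osc_spec = p53_waveform_spec("oscillatory"),
                       p53_rise_spec = p53_waveform_spec("rising")) {
  if (n_genes <= 0) stop("n_genes must be positive")
  if (abs(sum(mechanism_mix) - 1) > 1e-8)
    stop("mechanism_mix proportions must sum to 1")
  set.seed(seed)
  hourly <- 0:max(times)
  p53_osc <- gen_p53(p53_osc_spec, hourly)
  p53_rise <- gen_p53(p53_rise_spec, hourly)
  mechs <- sample(names(mechanism_mix), n_genes, replace = TRUE,
                  prob = mechanism_mix)
  genes <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    spec <- draw_mechanism(mechs[i])
    genes[[i]] <- simulate_gene(spec, p53_osc, p53_rise, noise,
                                n_replicates, times,
                                gene_id = sprintf("g%04d", i))
  }
  ids <- vapply(genes, `[[`, character(1), "gene_id")
  annotation <- setNames(
    sample(c("antiproliferative", "other"), n_genes, replace = TRUE,
           prob = c(0.25, 0.75)), ids)
  structure(list(genes = genes, p53_osc = p53_osc, p53_rise = p53_rise,
                 annotation = annotation, seed = seed, times = times),
            class = "cohort")
}

#' Flatten a cohort into an expression table for one modality
#'
#' @param cohort a `cohort` from [gen_cohort()].
#' @param modality `"mRNA"` or `"protein"`.
#' @return An `expression_table` data frame (wide by time).
#' @export
cohort_table <- function(cohort, modality = c("mRNA", "protein")) {
  modality <- match.arg(modality)
  long <- do.call(rbind, lapply(cohort$genes, `[[`, "data"))
  long <- long[long$modality == modality, ]
  times <- cohort$times
  wide <- stats::reshape(long[, c("gene_id", "condition", "replicate",
                                  "time", "level")],
                         idvar = c("gene_id", "condition", "replicate"),
                         timevar = "time", direction = "wide")
  names(wide) <- sub("^level\\.", "", names(wide))
  wide <- wide[order(wide$gene_id, wide$condition, wide$replicate), ]
  rownames(wide) <- NULL
  attr(wide, "reshapeWide") <- NULL
  attr(wide, "times") <- times
  attr(wide, "modality") <- modality
  class(wide) <- c("expression_table", "data.frame")
  wide
}

#' Mechanism ground-truth table of a cohort
#'
#' @param cohort a `cohort`.
#' @return Data frame: gene_id, mechanism, kinetic parameters.
#' @export
cohort_truth <- function(cohort) {
  do.call(rbind, lapply(cohort$genes, function(g) {
    k <- g$spec$kinetics
    data.frame(gene_id = g$gene_id, mechanism = g$mechanism,
               kp_mrna = k$kp_mrna, kd_mrna = k$kd_mrna,
               kp_prot = k$kp_prot, kd_prot = k$kd_prot, tdel = k$tdel,
               stringsAsFactors = FALSE)
  }))
}

#' Named motif presets for the exclusive-induction exemplars
#'
#' One fully specified generator setting per exemplar decoding strategy:
#' a post-transcriptional coherent FFL inducing protein under rising input
#' only (`cffl_posttranscriptional`), a transcriptional coherent FFL with
#' the same exclusivity acting one stage earlier (`cffl_transcriptional`),
#' an incoherent FFL inducing protein under oscillatory input only
#' (`iffl`), a medium translational activation threshold crossed only by
#' the rising-regime mRNA (`threshold_medium`), and a high threshold never
#' crossed (`threshold_high`).
#'
#' @return Named list of [mechanism_spec()] objects.
#' @export
motif_presets <- function() {
  arch <- archetype_specs()
  list(cffl_posttranscriptional = arch$d,
       cffl_transcriptional = arch$j,
       iffl = arch$h,
       threshold_medium = mechanism_spec(
         "threshold",
         kinetic_params(kd_mrna = 0.7, kd_prot = 0.2, tdel = 0.5),
         theta = "medium"),
       threshold_high = arch$k)
}

#' Archetype parameter sets for the dynamical categories
#'
#' Documented generator settings whose noiseless gene records classify to
#' the intended category letters: fast mRNA and protein turnover (a), fast
#' mRNA with stable protein (b), a post-transcriptional coherent FFL (d),
#' an incoherent FFL (h), a transcriptional coherent FFL (j), and a high
#' translational activation threshold (k).
#'
#' @return Named list (letters) of [mechanism_spec()] objects.
#' @export
archetype_specs <- function() {
  list(
    a = mechanism_spec("simple",
                       kinetic_params(kd_mrna = 0.85, kd_prot = 0.85,
                                      tdel = 0.5)),
    b = mechanism_spec("simple",
                       kinetic_params(kd_mrna = 0.85, kd_prot = 0.08,
                                      tdel = 0.5)),
    d = mechanism_spec("cffl_posttranscriptional",
                       kinetic_params(kd_mrna = 0.8, kd_prot = 0.25,
                                      tdel = 0.5)),
    h = mechanism_spec("iffl",
                       kinetic_params(kd_mrna = 0.8, kd_prot = 0.06,
                                      tdel = 2.5)),
    j = mechanism_spec("cffl_transcriptional",
                       kinetic_params(kd_mrna = 0.5, kd_prot = 0.5,
                                      tdel = 0.5)),
    k = mechanism_spec("threshold",
                       kinetic_params(kd_mrna = 0.7, kd_prot = 0.2,
                                      tdel = 0.5),
                       theta = "high"))
}
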