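# Shared fixtures built in code: hourly p53 references and small cohorts.

hourly <- 0:24

p53_osc_ref <- function() gen_p53(p53_waveform_spec("oscillatory"), hourly)
p53_rise_ref <- function() gen_p53(p53_waveform_spec("rising"), hourly)

# Flatten a list of gene records into one modality's expression table.
records_table <- function(records, modality, times = default_grid()) {
  long <- do.call(rbind, lapply(records, `[[`, "data"))
  sub <- long[long$modality == modality, ]
  wide <- stats::reshape(sub[, c("gene_id", "condition", "replicate",
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

# Replicate-mean trace of one gene/condition from a gene_record data frame.
record_mean <- function(record, modality, condition,
                        times = default_grid()) {
  d <- record$data
  vapply(times, function(t)
    mean(d$level[d$modality == modality & d$condition == condition &
                   d$time == t]), numeric(1))
}

# Independent step-up BH oracle: direct implementation of the step-up
# minimum over ranked p-values.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[o[i]] <- min(1, min(p[o][i:m] * m / (i:m)))
  adj
}

# Archetype records for the category round trip (noiseless, seeded).
archetype_records <- function(cv = 0) {
  po <- p53_osc_ref()
  pr <- p53_rise_ref()
  set.seed(101)
  specs <- archetype_specs()
  lapply(names(specs), function(nm)
    simulate_gene(specs[[nm]], po, pr, noise_model(cv),
                  gene_id = paste0("arch_", nm)))
}
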