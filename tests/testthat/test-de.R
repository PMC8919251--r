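test_that("basal-contrast t-test behaves at its boundaries", {
  expect_equal(ttest_vs_basal(c(1, 1), c(1, 1)), 1)
  expect_lt(ttest_vs_basal(c(10, 10.1), c(1, 1.01)), 0.05)
  # two-sided symmetry under group swap
  a <- c(1.2, 1.5); b <- c(2.4, 2.1)
  expect_equal(ttest_vs_basal(a, b), ttest_vs_basal(b, a))
  # zero-variance, unequal means: the noise-free limit is full significance
  expect_equal(ttest_vs_basal(c(2, 2), c(1, 1)), 0)
  expect_error(ttest_vs_basal(1, c(1, 2)), "replicates")
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
  set.seed(8)
  grid_p <- seq(0, 1, by = 0.01)
  for (len in 1:8) {
    for (rep in 1:50) {
      p <- sample(grid_p, len, replace = TRUE)
      expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
    }
  }
})

test_that("DE classification separates induced, repressed, and unchanged genes", {
  po <- p53_osc_ref(); pr <- p53_rise_ref()
  set.seed(21)
  induced <- simulate_gene(
    mechanism_spec("simple", kinetic_params(kd_mrna = 0.7, kd_prot = 0.7)),
    po, pr, noise_model(0.05), gene_id = "up")
  flat <- induced
  flat$gene_id <- "flat"
  flat$data$gene_id <- "flat"
  flat$data$level <- exp(rnorm(nrow(flat$data), 0, 0.02))
  house <- induced                     # housekeeping-like: tiny drift only
  house$gene_id <- "house"
  house$data$gene_id <- "house"
  house$data$level <- rep(c(rep(1, 10), 1.05), 8) *
    exp(rnorm(nrow(house$data), 0, 0.01))
  tab <- records_table(list(induced, flat, house), "mRNA")
  de <- select_de(tab, "rising", de_criteria("mRNA"))
  expect_equal(de$status[de$gene_id == "up"], "induced")
  expect_equal(de$status[de$gene_id == "flat"], "unchanged")
  expect_equal(de$status[de$gene_id == "house"], "unchanged")
  expect_true(all(de$min_q >= 0 & de$min_q <= 1))
  # a housekeeping-like protein below the 1.15 cut-off is not induced
  ptab <- records_table(list(house), "protein")
  dep <- select_de(ptab, "rising", de_criteria("protein"))
  expect_false(any(dep$status == "induced"))
})

test_that("tightening any DE threshold yields a subset", {
  cohort <- gen_cohort(40, noise = noise_model(0.1), seed = 17)
  tab <- cohort_table(cohort, "mRNA")
  base <- de_criteria("mRNA")
  loose <- induced_genes(select_de(tab, "rising", base))
  for (crit in list(de_criteria("mRNA", fc_threshold = 3),
                    de_criteria("mRNA", fdr_threshold = 0.01),
                    de_criteria("mRNA", pcc_threshold = 0.9))) {
    tight <- induced_genes(select_de(tab, "rising", crit))
    expect_true(all(tight %in% loose))
  }
})

test_that("DE sensitivity and specificity are stable across seeds", {
  sens <- spec <- numeric(2)
  for (i in 1:2) {
    seed <- c(51, 87)[i]
    cohort <- gen_cohort(250, mechanism_mix = c(simple = 1),
                         noise = noise_model(0.1), seed = seed)
    tab <- cohort_table(cohort, "mRNA")
    set.seed(seed + 1)
    null_rows <- tab[tab$gene_id %in% unique(tab$gene_id)[1:50], ]
    null_rows$gene_id <- paste0("null_", null_rows$gene_id)
    tcols <- as.character(attr(tab, "times"))
    null_rows[tcols] <- exp(matrix(rnorm(nrow(null_rows) * length(tcols),
                                         0, 0.1), nrow(null_rows)))
    both <- rbind(tab, null_rows)
    attributes(both)[c("times", "modality", "class")] <-
      attributes(tab)[c("times", "modality", "class")]
    de <- select_de(both, "rising", de_criteria("mRNA"))
    truly <- !grepl("^null_", de$gene_id)
    sens[i] <- mean(de$status[truly] == "induced")
    spec[i] <- mean(de$status[!truly] != "induced")
  }
  expect_gt(min(sens), 0.9)
  expect_gt(min(spec), 0.9)
  expect_lt(abs(sens[1] - sens[2]), 0.05)
  expect_lt(abs(spec[1] - spec[2]), 0.05)
})
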