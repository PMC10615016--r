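test_that("the same config and seed reproduce the cohort exactly", {
  a <- simulate_cohort(small_config(seed = 42))
  b <- simulate_cohort(small_config(seed = 42))
  expect_identical(a$counts, b$counts)
  expect_identical(a$sample_sheet, b$sample_sheet)
  expect_identical(a$truth$true_time, b$truth$true_time)
  c2 <- simulate_cohort(small_config(seed = 43))
  expect_false(identical(a$counts, c2$counts))
})

test_that("cohort structure: unique ids, controls at one pseudo-timepoint", {
  co <- simulate_cohort(small_config(seed = 7))
  sheet <- co$sample_sheet
  expect_false(anyDuplicated(sheet$sample_id) > 0)
  ctrl <- sheet[sheet$type == "control", ]
  expect_equal(unique(ctrl$timepoint), "baseline")
  expect_setequal(names(co$truth$groups),
                  unique(sheet$subject_id[sheet$type == "patient"]))
  # control columns only in the baseline matrix
  expect_true(all(ctrl$sample_id %in% colnames(co$counts$baseline)))
  expect_false(any(ctrl$sample_id %in% colnames(co$counts$month3)))
})

test_that("with all effects zero and alpha 0, gene means match libsize x mu", {
  mu <- 50
  co <- simulate_cohort(null_config(seed = 5, group_sizes = c(100L, 100L),
                                    mu = mu))
  counts <- co$counts$baseline
  pat <- names(co$truth$groups)
  ids <- paste0(pat, "_baseline")
  f <- co$truth$libsize[seq_along(ids)]
  # depth-corrected per-gene mean across 200 samples; Poisson variance
  scaled <- sweep(counts[, ids], 2L, f, "/")
  m <- rowMeans(scaled)
  se <- sqrt(mu * mean(1 / f) / length(ids))
  # per-gene means sit within the Poisson 3-SE band (99.7% of genes)
  expect_gt(mean(abs(m - mu) < 3 * se), 0.985)
  expect_lt(max(abs(m - mu)), 5 * se)
})

test_that("hazard_beta = 0 makes event times independent of group", {
  t1 <- c(); t2 <- c()
  for (s in 1:50) {
    co <- simulate_cohort(null_config(seed = 100 + s,
                                      group_sizes = c(10L, 10L)))
    g <- co$truth$groups
    t1 <- c(t1, co$truth$true_time[g == "EpiGroup1"])
    t2 <- c(t2, co$truth$true_time[g == "EpiGroup2"])
  }
  expect_gt(suppressWarnings(stats::ks.test(t1, t2)$p.value), 0.01)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(baseline_mu = c(10, -1)), "baseline_mu")
  expect_error(simulation_config(target_sets = list(a = integer(0))),
               "empty target")
  expect_error(simulation_config(group_sizes = c(0L, 5L)), "group sizes")
  expect_error(simulation_config(censor_horizon = 0), "censor_horizon")
  expect_error(simulate_cohort(
    simulation_config(n_genes = 100L,
                      target_sets = list(a = 1:10),
                      signature_genes_per_group = 0L,
                      effect_log2fc = data.frame(
                        set = "missing_set", group = "EpiGroup1",
                        timepoint = "baseline", log2fc = 1))),
    "unknown target set")
})

test_that("default hazard calibration yields HR 3 across the score split", {
  co <- simulate_cohort(small_config(seed = 9))
  ts <- co$truth$true_score
  # the calibration split is the measured-score median split
  hi <- co$truth$calibration_scores > median(co$truth$calibration_scores)
  gap <- mean(ts[hi]) - mean(ts[!hi])
  expect_equal(exp(co$truth$hazard_beta * gap), 3, tolerance = 1e-12)
  expect_true(all(co$truth$time_months <= 24))
})

test_that("simulated fragments sit fully inside their gene", {
  genes <- toy_genes()
  fr <- simulate_fragments(genes, c(5L, 3L, 2L), seed = 1)
  expect_equal(nrow(fr), 10L)
  expect_true(all(fr$end - fr$start == 167L))
  byg <- rep(seq_len(3L), c(5L, 3L, 2L))
  expect_true(all(fr$start >= genes$start[byg]))
  expect_true(all(fr$end <= genes$end[byg]))
  # zero counts give an empty BED
  expect_equal(nrow(simulate_fragments(genes, c(0L, 0L, 0L), seed = 1)), 0L)
  # genes shorter than the fragment are refused by name
  short <- data.frame(gene_id = "tiny", chrom = "chr1",
                      start = 0L, end = 100L)
  expect_error(simulate_fragments(short, 1L, seed = 1), "tiny")
})

test_that("spike-in simulation respects its rates", {
  zero_bg <- simulate_spikein(1000, 1000, 0.5, 0, seed = 1)
  expect_equal(zero_bg$reads[zero_bg$class %in% c("C", "mC")], c(0L, 0L))
  no_hmc <- simulate_spikein(0, 1000, 0.9, 0.01, seed = 1)
  expect_equal(no_hmc$reads[no_hmc$class == "hmC"], 0L)
  expect_error(simulate_spikein(10, 10, 1.5, 0, seed = 1), "rates")
  # expected fold enrichment 0.5 / 0.004 = 125 over replicates
  folds <- vapply(1:100, function(s) {
    r <- simulate_spikein(2e5, 2e5, 0.5, 0.004, seed = s)
    spikein_enrichment(r)$fold_enrichment
  }, 0)
  se <- stats::sd(folds) / 10
  expect_lt(abs(mean(folds) - 125), 3 * se)
})
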