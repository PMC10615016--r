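test_that("pooled control is the per-gene mean over control columns", {
  m <- matrix(c(2, 10, 4, 20, 6, 30), 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2", "p1")))
  expect_equal(pooled_control(m, c("c1", "c2")), c(g1 = 3, g2 = 15))
  expect_equal(pooled_control(m, "c1"), m[, "c1"])
  expect_equal(pooled_control(m, c("c2", "c1")),
               pooled_control(m, c("c1", "c2")))
  expect_error(pooled_control(m, c("c1", "nope")), "nope")
})

test_that("activity score reproduces the exact-formula fixtures", {
  patient <- c(g1 = 4, g2 = 8)
  control <- c(g1 = 1, g2 = 2)
  out <- activity_score(patient, control, c("g1", "g2"), pseudocount = 0)
  expect_equal(out$score, 200)                # 100 * (2 + 2) / 2
  expect_equal(out$n_genes_used, 2)
  # patient identical to control scores zero
  expect_equal(activity_score(control, control, c("g1", "g2"))$score, 0)
  # doubling every patient count adds exactly 100 (pseudocount 0)
  out2 <- activity_score(2 * patient, control, c("g1", "g2"),
                         pseudocount = 0)
  expect_equal(out2$score, out$score + 100)
  # global rescaling of both sides cancels (ratio invariance)
  out3 <- activity_score(7 * patient, 7 * control, c("g1", "g2"),
                         pseudocount = 0)
  expect_equal(out3$score, out$score)
})

test_that("score matches the brute-force mean-of-log-ratios oracle", {
  set.seed(12)
  for (i in 1:25) {
    genes <- paste0("g", 1:20)
    patient <- stats::setNames(runif(20, 0, 500), genes)
    control <- stats::setNames(runif(20, 1, 500), genes)
    pick <- sample(genes, sample(3:20, 1))
    expect_equal(activity_score(patient, control, pick)$score,
                 brute_score(patient, control, pick),
                 tolerance = 1e-12)
  }
})

test_that("missing genes are dropped with a warning, empty sets error", {
  patient <- c(g1 = 4, g2 = 8)
  control <- c(g1 = 1, g3 = 2)
  expect_warning(out <- activity_score(patient, control,
                                       c("g1", "g2", "g3"), "mySet"),
                 "missing")
  expect_equal(out$n_genes_used, 1)
  expect_error(
    suppressWarnings(activity_score(patient, control, "g9", "mySet")),
    "mySet")
  expect_error(activity_score(c(g1 = 0), c(g1 = 1), "g1",
                              pseudocount = 0), "zero normalized count")
})

test_that("score_matrix enumerates all sample x set pairs deterministically", {
  m <- matrix(c(2, 10, 4, 20, 6, 30), 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2", "p1")))
  ctrl <- pooled_control(m, c("c1", "c2"))
  sets <- list(s1 = c("g1", "g2"), s2 = "g1")
  tab <- score_matrix(m, ctrl, sets, c("p1", "c1"))
  expect_equal(nrow(tab), 4)
  one <- activity_score(m[, "p1"], ctrl, sets$s1)
  expect_equal(tab$score[tab$sample_id == "p1" & tab$set == "s1"],
               one$score)
})

test_that("null cohort scores are centered near zero", {
  co <- simulate_cohort(null_config(seed = 77, n_genes = 300,
                                    group_sizes = c(25L, 25L), mu = 50))
  counts <- co$counts$baseline
  sf <- size_factors(counts)
  nm <- normalize_counts(counts, sf)
  sheet <- co$sample_sheet
  ctrl <- pooled_control(nm, sheet$sample_id[sheet$type == "control"])
  pat <- sheet$sample_id[sheet$type == "patient"]
  tab <- score_matrix(nm, ctrl, co$truth$target_sets, pat)
  expect_lt(abs(mean(tab$score)), 2)
  # controls scored against their own pool are also near zero
  ctab <- score_matrix(nm, ctrl, co$truth$target_sets,
                       sheet$sample_id[sheet$type == "control"])
  expect_lt(abs(mean(ctab$score)), 2)
})

test_that("a uniform +delta log2 shift moves the score by 100*delta", {
  set.seed(13)
  genes <- paste0("g", 1:30)
  patient <- stats::setNames(runif(30, 10, 100), genes)
  control <- stats::setNames(runif(30, 10, 100), genes)
  base <- activity_score(patient, control, genes, pseudocount = 0)$score
  shifted <- activity_score(patient * 2^0.37, control, genes,
                            pseudocount = 0)$score
  expect_equal(shifted - base, 37, tolerance = 1e-9)
})

test_that("group comparison summarizes means, SDs and Welch contrasts", {
  tab <- data.frame(sample_id = paste0("s", 1:8),
                    set = "s1",
                    score = c(1, 2, 3, 4, 1, 2, 3, 4),
                    n_genes_used = 10)
  grouping <- stats::setNames(rep(c("a", "b"), each = 4), tab$sample_id)
  out <- compare_scores(tab, grouping)
  expect_equal(out$summary$mean, c(2.5, 2.5))
  expect_equal(out$contrasts$p, 1)            # identical groups
  expect_equal(out$contrasts$mean_diff, 0)
  # singleton group: contrast skipped with a warning
  g2 <- stats::setNames(c(rep("a", 7), "b"), tab$sample_id)
  expect_warning(out2 <- compare_scores(tab, g2), "singleton")
  expect_true(is.na(out2$summary$sd[out2$summary$group == "b"]))
  expect_null(out2$contrasts)
})
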