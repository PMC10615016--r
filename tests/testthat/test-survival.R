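test_that("KM estimate matches hand-computed product limits", {
  # no events: survival stays at 1
  km0 <- km_estimate(c(3, 8, 14), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  # two subjects, events at 1 and 2
  km <- km_estimate(c(1, 2), c(1, 1))
  expect_equal(km$surv, c(0.5, 0))
  expect_equal(km_surv_at(km, 1.5), 0.5)
  expect_equal(km_surv_at(km, 0.5), 1)
  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(41)
  t <- rexp(40, 0.1)
  km <- km_estimate(t, rep(1, 40))
  for (q in c(2, 5, 12)) {
    expect_equal(km_surv_at(km, q), mean(t > q))
  }
})

test_that("KM agrees with the survival package", {
  skip_if_not_installed("survival")
  set.seed(42)
  t <- round(rexp(30, 0.08), 1) + 0.1
  e <- rbinom(30, 1, 0.7)
  km <- km_estimate(t, e)
  fit <- survival::survfit(survival::Surv(t, e) ~ 1)
  sm <- summary(fit, times = km$time)
  expect_equal(km$surv, sm$surv, tolerance = 1e-10)
  expect_equal(km$se[km$n_event > 0],
               sm$std.err[km$n_event > 0], tolerance = 1e-6)
})

test_that("log-rank matches the two-subject hand tabulation", {
  out <- logrank_test(c(1, 2), c(1, 1), c("A", "B"))
  expect_equal(out$chi2, 1.0, tolerance = 1e-12)
  expect_equal(out$p, pchisq(1, 1, lower.tail = FALSE))
  expect_equal(sum(out$observed - out$expected), 0, tolerance = 1e-9)
  # identical data in both strata: no signal
  t <- c(1, 3, 5, 7); e <- c(1, 0, 1, 1)
  out2 <- logrank_test(c(t, t), c(e, e), rep(c("A", "B"), each = 4))
  expect_equal(out2$chi2, 0, tolerance = 1e-12)
  expect_equal(out2$p, 1)
  expect_error(logrank_test(c(1, 2), c(0, 0), c("A", "B")), "event")
})

test_that("log-rank agrees with survdiff", {
  skip_if_not_installed("survival")
  set.seed(43)
  t <- rexp(50, 0.1); e <- rbinom(50, 1, 0.8)
  g <- rep(c("A", "B"), 25)
  ours <- logrank_test(t, e, g)
  ref <- survival::survdiff(survival::Surv(t, e) ~ g)
  expect_equal(ours$chi2, unname(ref$chisq), tolerance = 1e-9)
})

test_that("Cox fit maximizes the partial likelihood (grid oracle)", {
  set.seed(44)
  x <- rep(c(0, 1), each = 10)
  t <- rexp(20, 0.05 * exp(0.9 * x))
  e <- as.integer(t < 30); t <- pmin(t, 30)
  fit <- cox_fit(t, e, x)
  grid <- seq(-4, 4, by = 1e-4)
  ll <- vapply(grid, function(b)
    cfhmc:::cox_loglik(b, t, e, x)$ll, 0)
  expect_equal(fit$log_hr, grid[which.max(ll)], tolerance = 1e-4)
  expect_equal(fit$hr, exp(fit$log_hr))
  # relabeling the covariate inverts the hazard ratio
  flipped <- cox_fit(t, e, 1 - x)
  expect_equal(flipped$log_hr, -fit$log_hr, tolerance = 1e-7)
})

test_that("Cox agrees with coxph under Breslow ties", {
  skip_if_not_installed("survival")
  set.seed(45)
  x <- rbinom(40, 1, 0.5)
  t <- round(rexp(40, 0.04 * exp(0.7 * x)), 1) + 0.1   # induce ties
  e <- as.integer(t < 25); t <- pmin(t, 25)
  fit <- cox_fit(t, e, x)
  ref <- survival::coxph(survival::Surv(t, e) ~ x, ties = "breslow")
  expect_equal(fit$log_hr, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$se, unname(sqrt(vcov(ref)[1, 1])), tolerance = 1e-6)
})

test_that("Cox null covariate stays within 3 SE of zero", {
  set.seed(46)
  x <- rbinom(60, 1, 0.5)
  t <- rexp(60, 0.08)
  e <- as.integer(t < 24); t <- pmin(t, 24)
  fit <- cox_fit(t, e, x)
  expect_lt(abs(fit$log_hr), 3 * fit$se)
})

test_that("complete separation is flagged and capped", {
  t <- c(1, 2, 3, 4, 11, 12, 13, 14)
  e <- rep(1, 8)
  x <- rep(c(1, 0), each = 4)                 # all early events are x = 1
  expect_warning(fit <- cox_fit(t, e, x), "monotone")
  expect_true(fit$flagged)
  expect_lte(abs(fit$log_hr), 10)
})

test_that("median dichotomization follows the documented tie rule", {
  lab <- dichotomize_by_median(c(a = 1, b = 2, c = 3, d = 4))
  expect_equal(lab, c(a = "low", b = "low", c = "high", d = "high"))
  lab2 <- dichotomize_by_median(c(a = 1, b = 2, c = 2, d = 4))
  expect_equal(unname(lab2), c("low", "low", "low", "high"))
  x <- c(a = 5, b = 1, c = 9, d = 2)
  expect_equal(dichotomize_by_median(x)[names(x)],
               dichotomize_by_median(x[c(3, 1, 4, 2)])[names(x)])
  expect_error(dichotomize_by_median(c(a = 2, b = 2)), "identical")
  tab <- data.frame(sample_id = letters[1:4], set = "s",
                    score = 1:4, n_genes_used = 5)
  expect_equal(unname(dichotomize_by_median(tab, "s")),
               c("low", "low", "high", "high"))
})

test_that("ANCOVA reduces to one-way ANOVA with orthogonal covariates", {
  set.seed(47)
  group <- rep(c("a", "b"), each = 10)
  # covariate orthogonal to the group indicator by construction
  cov1 <- rep(c(-1, 1), 10)
  score <- ifelse(group == "a", 0, 2) + rnorm(20)
  score <- score - (cov1 %*% score / sum(cov1^2))[1] * cov1 # orthogonalize
  out <- ancova_adjust(score, group, data.frame(cov1 = cov1))
  ref <- anova(lm(score ~ factor(group)))
  # same sums of squares as one-way ANOVA; the F ratio differs only by
  # the residual-df bookkeeping of the extra (inert) covariate column
  expect_equal(out$F * 18 / 17, ref$`F value`[1], tolerance = 1e-9)
  # hand fixture: n = 6, one covariate, explicit normal equations
  s <- c(3, 5, 4, 8, 9, 10)
  g <- rep(c("a", "b"), each = 3)
  cv <- c(1, 2, 3, 2, 3, 4)
  X_full <- cbind(1, cv, g == "b")
  X_red <- cbind(1, cv)
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% s)
    sum((s - X %*% beta)^2)
  }
  F_hand <- ((rss(X_red) - rss(X_full)) / 1) / (rss(X_full) / (6 - 3))
  out2 <- ancova_adjust(s, g, data.frame(cv = cv))
  expect_equal(out2$F, F_hand, tolerance = 1e-9)
})

test_that("a group fully absorbed by a covariate has zero adjusted effect", {
  g <- rep(c("a", "b"), each = 4)
  cov1 <- as.numeric(g == "b")
  score <- cov1                                # score = covariate = group
  expect_warning(out <- ancova_adjust(score, g, data.frame(cov1 = cov1)),
                 "collinear")
  expect_equal(out$F, 0)
  expect_equal(out$p, 1)
  # collinear covariates themselves are an error
  expect_error(ancova_adjust(rnorm(8), g,
                             data.frame(c1 = cov1, c2 = 2 * cov1)),
               "rank-deficient")
})
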