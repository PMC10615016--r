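check_survival <- function(time, event) {
  if (any(time <= 0)) stop("survival times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0 (censored) or 1")
  invisible(NULL)
}

#' Kaplan-Meier product-limit estimate
#'
#' Survival steps down at each distinct event time; subjects censored
#' at a tied time are still at risk for the tie's events (the standard
#' convention). The Greenwood formula gives the variance at each step.
#'
#' @param time positive follow-up times (months).
#' @param event 1 = progression, 0 = censored.
#' @return data frame of class `"km_curve"`: time, n_risk, n_event,
#'   n_censor, surv, var (Greenwood), se — one row per distinct time.
#' @export
km_estimate <- function(time, event) {
  check_survival(time, event)
  if (length(time) < 1L) stop("need at least one subject")
  tt <- sort(unique(time))
  n_risk <- vapply(tt, function(t) sum(time >= t), 0)
  n_event <- vapply(tt, function(t) sum(time == t & event == 1), 0)
  n_censor <- vapply(tt, function(t) sum(time == t & event == 0), 0)
  surv <- cumprod(1 - n_event / n_risk)
  gw <- ifelse(n_risk > n_event,
               n_event / (n_risk * (n_risk - n_event)), 0)
  var <- surv^2 * cumsum(gw)
  structure(data.frame(time = tt, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, surv = surv, var = var,
                       se = sqrt(var)),
            class = c("km_curve", "data.frame"))
}

#' Survival probability at a time from a KM curve
#' @param km a [km_estimate()] result.
#' @param t time at which to evaluate S(t).
#' @return numeric scalar (1 before the first event).
#' @export
km_surv_at <- function(km, t) {
  i <- which(km$time <= t)
  if (!length(i)) return(1)
  km$surv[max(i)]
}

#' Two-group Mantel-Cox log-rank test
#'
#' At each distinct event time, compares observed events in group 1
#' with the hypergeometric expectation given the risk sets;
#' `chi2 = (sum(O - E))^2 / sum(V)` on 1 df.
#'
#' @param time,event as in [km_estimate()].
#' @param group two-level vector of stratum labels.
#' @return list: chi2, df, p, and per-group observed/expected event
#'   counts.
#' @export
logrank_test <- function(time, event, group) {
  check_survival(time, event)
  g <- factor(group)
  if (nlevels(g) != 2L) stop("exactly two strata are required")
  if (sum(event) < 1L) stop("need at least one event")
  i1 <- g == levels(g)[1L]
  tt <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0; o1 <- 0; e1 <- 0
  for (t in tt) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & i1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & i1)
    e <- d * n1 / n
    o1 <- o1 + d1; e1 <- e1 + e
    o_minus_e <- o_minus_e + (d1 - e)
    if (n > 1L)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v == 0) {
    warning("zero log-rank variance; p set to 1")
    return(list(chi2 = 0, df = 1L, p = 1,
                observed = c(o1, sum(event) - o1),
                expected = c(e1, sum(event) - e1)))
  }
  chi2 <- o_minus_e^2 / v
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1L,
                                               lower.tail = FALSE),
       observed = stats::setNames(c(o1, sum(event) - o1), levels(g)),
       expected = stats::setNames(c(e1, sum(event) - e1), levels(g)))
}

# Breslow partial log-likelihood and derivatives for one covariate
cox_loglik <- function(beta, time, event, x) {
  eta <- x * beta
  r <- exp(eta)
  tt <- sort(unique(time[event == 1]))
  ll <- 0; u <- 0; info <- 0
  for (t in tt) {
    at_risk <- time >= t
    ev <- time == t & event == 1
    d <- sum(ev)
    s0 <- sum(r[at_risk])
    s1 <- sum(r[at_risk] * x[at_risk])
    s2 <- sum(r[at_risk] * x[at_risk]^2)
    ll <- ll + sum(eta[ev]) - d * log(s0)
    u <- u + sum(x[ev]) - d * s1 / s0
    info <- info + d * (s2 / s0 - (s1 / s0)^2)
  }
  list(ll = ll, score = u, info = info)
}

#' Cox proportional-hazards fit (single covariate)
#'
#' Maximizes the Breslow partial likelihood by Newton-Raphson
#' (tolerance 1e-8, at most 50 iterations) and reports the Wald test
#' from the observed information. A monotone likelihood (complete
#' separation of event times by the covariate) is flagged and the
#' estimate capped at |log HR| <= 10.
#'
#' @param time,event as in [km_estimate()].
#' @param x numeric or two-level covariate (a factor/character is coded
#'   0/1 so HR is level 2 vs level 1).
#' @return list of class `"cox_result"`: log_hr, se, hr, z, p,
#'   iterations, flagged.
#' @export
cox_fit <- function(time, event, x) {
  check_survival(time, event)
  if (is.character(x) || is.factor(x)) {
    f <- factor(x)
    if (nlevels(f) != 2L) stop("a two-level covariate is required")
    x <- as.numeric(f) - 1
  }
  if (stats::var(x) == 0) stop("constant covariate")
  beta <- 0; flagged <- FALSE; it <- 0L
  for (it in seq_len(50L)) {
    d <- cox_loglik(beta, time, event, x)
    if (d$info <= 0) { flagged <- TRUE; break }
    step <- d$score / d$info
    beta <- beta + step
    if (abs(beta) > 10) {
      beta <- sign(beta) * 10
      flagged <- TRUE
      warning("monotone partial likelihood: |log HR| capped at 10")
      break
    }
    if (abs(step) < 1e-8) break
  }
  d <- cox_loglik(beta, time, event, x)
  se <- if (d$info > 0) 1 / sqrt(d$info) else NA_real_
  z <- beta / se
  structure(list(log_hr = beta, se = se, hr = exp(beta), z = z,
                 p = 2 * stats::pnorm(-abs(z)), iterations = it,
                 flagged = flagged),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH: HR = %.3f (log HR %.4f +/- %.4f), Wald p = %.4g%s\n",
              x$hr, x$log_hr, x$se, x$p,
              if (x$flagged) " [monotone likelihood]" else ""))
  invisible(x)
}

#' Split samples at the median activity score
#'
#' Labels a sample "high" when its score exceeds the median and "low"
#' otherwise; scores exactly at the median go to the low stratum
#' (deterministic tie rule, conservative for the high-risk group). The
#' even-n median is the mean of the two middle values.
#'
#' @param scores named numeric vector, or a [score_matrix()] table with
#'   `set_name` selecting one gene set.
#' @param set_name gene-set name when `scores` is a table.
#' @return named character vector of "high"/"low" labels.
#' @export
dichotomize_by_median <- function(scores, set_name = NULL) {
  if (is.data.frame(scores)) {
    if (is.null(set_name)) stop("set_name is required for a score table")
    d <- scores[scores$set == set_name, ]
    if (nrow(d) == 0L) stop("no scores for set '", set_name, "'")
    scores <- stats::setNames(d$score, d$sample_id)
  }
  if (length(scores) < 2L) stop("need at least two samples")
  med <- stats::median(scores)
  if (all(scores == med)) stop("all scores identical: no median split")
  stats::setNames(ifelse(scores > med, "high", "low"), names(scores))
}

#' ANCOVA adjustment of a group effect on activity scores
#'
#' Ordinary least squares of the score on the group indicator plus
#' clinical covariates (e.g. baseline PSA and ctDNA fraction); the
#' group effect is the partial F test against the covariates-only
#' model.
#'
#' @param scores numeric response vector.
#' @param group group labels (any number of levels).
#' @param covariates data frame of numeric covariates, rows parallel to
#'   `scores`.
#' @return list: F, df1, df2, p, fit (the full `lm`).
#' @export
ancova_adjust <- function(scores, group, covariates) {
  covariates <- as.data.frame(covariates)
  if (length(scores) <= ncol(covariates) + length(unique(group)) + 1L)
    stop("too few observations for the model terms")
  d <- data.frame(.score = scores, covariates, .group = factor(group))
  reduced <- stats::lm(.score ~ . - .group, data = d)
  if (any(is.na(stats::coef(reduced)))) {
    bad <- names(stats::coef(reduced))[is.na(stats::coef(reduced))]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  full <- stats::lm(.score ~ ., data = d)
  co <- stats::coef(full)
  if (all(is.na(co[grep("^\\.group", names(co))]))) {
    # group indicator fully absorbed by the covariates: no adjusted effect
    warning("group term collinear with covariates; adjusted F is 0")
    return(list(F = 0, df1 = 0L,
                df2 = stats::df.residual(reduced), p = 1, fit = full))
  }
  a <- stats::anova(reduced, full)
  list(F = a$F[2L], df1 = a$Df[2L], df2 = a$Res.Df[2L],
       p = a$`Pr(>F)`[2L], fit = full)
}
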