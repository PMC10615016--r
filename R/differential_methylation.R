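row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1L)
}

check_two_groups <- function(group_labels, n_cols) {
  if (length(group_labels) != n_cols)
    stop("group_labels must match the number of samples")
  g <- factor(group_labels)
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  if (any(table(g) < 2L)) stop("each group needs at least 2 samples")
  g
}

#' Negative-binomial Wald test for differential 5hmC methylation
#'
#' Per-gene two-group comparison on size-factor-normalized counts. The
#' NB dispersion (Var = mu + alpha * mu^2) is estimated per gene by
#' method of moments on the within-group pooled variance, then smoothed
#' by the median within 50 mean-rank bins and floored at 1e-8. The log2
#' fold change uses a pseudo-mean of 0.5; its standard error comes from
#' the delta method under the NB variance, giving a Wald z and a
#' two-sided normal p-value, BH-adjusted across genes.
#'
#' @param counts gene x sample raw count matrix.
#' @param factors per-sample size factors (see [size_factors()]).
#' @param group_labels two-level vector parallel to columns; fold
#'   changes are level 2 vs level 1.
#' @param fdr_cutoff FDR threshold used for the direction column
#'   (default 0.1, strict `<`).
#' @return a DMG table: data frame with gene_id, log2fc, se, stat, p,
#'   fdr, direction (hyper / hypo / ns).
#' @export
nb_wald_test <- function(counts, factors, group_labels, fdr_cutoff = 0.1) {
  g <- check_two_groups(group_labels, ncol(counts))
  norm <- normalize_counts(counts, factors)
  i1 <- g == levels(g)[1L]
  i2 <- !i1
  if (all(counts[, i1] == 0) || all(counts[, i2] == 0))
    stop("a group has all-zero counts in every gene")
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(norm[, i1, drop = FALSE])
  m2 <- rowMeans(norm[, i2, drop = FALSE])
  v1 <- row_vars(norm[, i1, drop = FALSE])
  v2 <- row_vars(norm[, i2, drop = FALSE])
  vpool <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
  mpool <- (n1 * m1 + n2 * m2) / (n1 + n2)
  alpha_raw <- (vpool - mpool) / mpool^2
  alpha <- smooth_dispersion(alpha_raw, mpool)

  eps <- 0.5
  log2fc <- log2((m2 + eps) / (m1 + eps))
  var_mean <- function(m, n) (m + alpha * m^2) / n
  se <- sqrt(var_mean(m1, n1) / (m1 + eps)^2 +
             var_mean(m2, n2) / (m2 + eps)^2) / log(2)
  stat <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * stats::pnorm(-abs(stat))
  finish_dmg_table(rownames(counts), log2fc, se, stat, p, fdr_cutoff)
}

# median-smooth method-of-moments dispersions in mean-rank bins
smooth_dispersion <- function(alpha_raw, means, n_bins = 50L, floor = 1e-8) {
  alpha_raw[!is.finite(alpha_raw)] <- 0
  n <- length(alpha_raw)
  if (n <= n_bins) return(pmax(alpha_raw, floor))
  bins <- ceiling(rank(means, ties.method = "first") / (n / n_bins))
  med <- tapply(alpha_raw, bins, stats::median)
  pmax(as.numeric(med[as.character(bins)]), floor)
}

#' Welch t-test on variance-stabilized values
#'
#' Per-gene two-group Welch test with Satterthwaite degrees of freedom,
#' run on the [stabilize()]d matrix so the effect column is a
#' difference of log2 values. Degenerate variance conventions: both
#' groups constant with equal means gives p = 1; zero variance with
#' unequal means gives p = 0.
#'
#' @param transformed stabilized gene x sample matrix.
#' @inheritParams nb_wald_test
#' @return DMG table as in [nb_wald_test()] (stat = Welch t).
#' @export
welch_t_test <- function(transformed, group_labels, fdr_cutoff = 0.1) {
  g <- check_two_groups(group_labels, ncol(transformed))
  i1 <- g == levels(g)[1L]
  x1 <- transformed[, i1, drop = FALSE]
  x2 <- transformed[, !i1, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- row_vars(x1); v2 <- row_vars(x2)
  w1 <- v1 / n1; w2 <- v2 / n2
  se <- sqrt(w1 + w2)
  stat <- (m2 - m1) / se
  df <- (w1 + w2)^2 / (w1^2 / (n1 - 1L) + w2^2 / (n2 - 1L))
  p <- 2 * stats::pt(-abs(stat), df)
  zero <- se == 0
  if (any(zero)) {
    eq <- zero & m1 == m2
    stat[eq] <- 0; p[eq] <- 1
    ne <- zero & m1 != m2
    stat[ne] <- sign(m2 - m1)[ne] * Inf; p[ne] <- 0
  }
  finish_dmg_table(rownames(transformed), m2 - m1, se, stat, p, fdr_cutoff)
}

finish_dmg_table <- function(gene_id, log2fc, se, stat, p, fdr_cutoff) {
  fdr <- bh_fdr(p)
  direction <- ifelse(fdr < fdr_cutoff & log2fc > 0, "hyper",
               ifelse(fdr < fdr_cutoff & log2fc < 0, "hypo", "ns"))
  data.frame(gene_id = gene_id, log2fc = log2fc, se = se, stat = stat,
             p = p, fdr = fdr, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min(1, min_{j >= i} p_(j) * m / j)`, returned in the
#' original order.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return adjusted values in [0, 1], same order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  if (m == 0L) return(numeric(0))
  o <- order(pvalues)
  q <- pmin(1, rev(cummin(rev(pvalues[o] * m / seq_len(m)))))
  q[order(o)]
}

#' Partition a DMG table at an FDR cutoff
#'
#' Hypermethylated: fdr < cutoff and log2fc > 0; hypomethylated:
#' fdr < cutoff and log2fc < 0; everything else non-significant. The
#' cutoff is strict (fdr exactly at the cutoff is not called).
#'
#' @param table DMG table from [nb_wald_test()] or [welch_t_test()].
#' @param fdr_cutoff FDR threshold (default 0.1).
#' @return list with gene-id vectors `hyper`, `hypo`, `ns` and the
#'   re-labelled `table`.
#' @export
call_dmgs <- function(table, fdr_cutoff = 0.1) {
  need <- c("gene_id", "log2fc", "fdr")
  if (!all(need %in% names(table)))
    stop("DMG table needs columns: ", paste(need, collapse = ", "))
  direction <- ifelse(table$fdr < fdr_cutoff & table$log2fc > 0, "hyper",
               ifelse(table$fdr < fdr_cutoff & table$log2fc < 0, "hypo",
                      "ns"))
  table$direction <- direction
  list(hyper = table$gene_id[direction == "hyper"],
       hypo = table$gene_id[direction == "hypo"],
       ns = table$gene_id[direction == "ns"],
       table = table)
}
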