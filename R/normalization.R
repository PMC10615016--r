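#' Filter genes by median raw count
#'
#' Keeps genes whose median raw read count across samples reaches the
#' threshold (default 8, inclusive); the even-n median is the mean of
#' the two middle values.
#'
#' @param counts gene x sample count matrix.
#' @param min_median minimum per-gene median raw count (default 8).
#' @return the row-filtered count matrix.
#' @export
filter_genes <- function(counts, min_median = 8) {
  validate_counts(counts)
  med <- apply(counts, 1L, stats::median)
  keep <- med >= min_median
  if (!any(keep))
    stop("no gene passes median >= ", min_median,
         "; lower min_median or check the input")
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes
#' (genes with a positive count in every sample) of the ratio of the
#' sample's count to the gene's geometric mean across samples. Factors
#' are rescaled to geometric mean 1 so they are comparable across
#' matrices.
#'
#' @param counts gene x sample count matrix.
#' @return named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts) {
  validate_counts(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene is positive in every sample; pre-filter the matrix")
  logc <- log(counts[pos, , drop = FALSE])
  logref <- rowMeans(logc)
  f <- apply(logc, 2L, function(col) exp(stats::median(col - logref)))
  f <- f / exp(mean(log(f)))
  f
}

#' Divide counts by size factors
#'
#' @param counts gene x sample count matrix.
#' @param factors named per-sample size factors covering every column.
#' @return normalized matrix (counts / factor, columnwise).
#' @export
normalize_counts <- function(counts, factors) {
  missing <- setdiff(colnames(counts), names(factors))
  if (length(missing))
    stop("missing size factor for sample(s): ",
         paste(missing, collapse = ", "))
  if (any(factors <= 0)) stop("size factors must be positive")
  sweep(counts, 2L, factors[colnames(counts)], "/")
}

#' Shifted-log variance-stabilizing transform
#'
#' Elementwise `log2(value + pseudocount)` of a normalized matrix — a
#' simple variance-stabilizing transform used before clustering and
#' visualization. It is not the parametric dispersion-trend VST of
#' count-model packages; see the methods vignette for why the simple
#' transform suffices here.
#'
#' @param normalized normalized (non-negative) matrix.
#' @param pseudocount positive offset added before the log (default 1).
#' @return transformed matrix.
#' @export
stabilize <- function(normalized, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  log2(normalized + pseudocount)
}
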