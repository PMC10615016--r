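#' Spike-in enrichment QC
#'
#' Computes copy-normalized capture rates for the C / 5mC / 5hmC
#' spike-in amplicon classes and the fold enrichment of the 5hmC class
#' over the mean of the two unmodified-background classes. A library
#' passes when fold enrichment reaches `min_fold` (inclusive). Zero
#' background with non-zero 5hmC reads passes with an infinite-fold
#' flag; no reads in any class fails with reason "no spike-in signal".
#'
#' @param reads data frame with columns class ("C", "mC", "hmC"),
#'   copies, reads — e.g. from [simulate_spikein()] or a spike-in TSV.
#' @param min_fold pass threshold on fold enrichment (default 100).
#' @return list of class `"spikein_report"`: reads_c, reads_mc,
#'   reads_hmc, copies, rates, fold_enrichment, infinite_fold, pass,
#'   reason.
#' @export
spikein_enrichment <- function(reads, min_fold = 100) {
  need <- c("C", "mC", "hmC")
  if (!all(need %in% reads$class))
    stop("spike-in table needs classes C, mC and hmC")
  row <- function(cl) reads[match(cl, reads$class), ]
  copies <- vapply(need, function(cl) row(cl)$copies, 0)
  nreads <- vapply(need, function(cl) row(cl)$reads, 0)
  if (any(copies <= 0)) stop("configuration error: zero spike-in copies")
  if (any(nreads < 0)) stop("negative read counts")
  rates <- nreads / copies
  bg <- mean(rates[c("C", "mC")])
  if (all(nreads == 0)) {
    fold <- NA_real_; inf_fold <- FALSE; pass <- FALSE
    reason <- "no spike-in signal"
  } else if (bg == 0) {
    fold <- Inf; inf_fold <- TRUE; pass <- TRUE
    reason <- "zero background"
  } else {
    fold <- rates[["hmC"]] / bg
    inf_fold <- FALSE
    pass <- fold >= min_fold
    reason <- if (pass) "ok" else "fold enrichment below threshold"
  }
  structure(list(reads_c = nreads[["C"]], reads_mc = nreads[["mC"]],
                 reads_hmc = nreads[["hmC"]], copies = copies,
                 rates = rates, fold_enrichment = fold,
                 infinite_fold = inf_fold, pass = pass, reason = reason),
            class = "spikein_report")
}

#' @export
print.spikein_report <- function(x, ...) {
  cat(sprintf(
    "spike-in QC: hmC %d, C %d, mC %d reads; fold enrichment %s; %s\n",
    x$reads_hmc, x$reads_c, x$reads_mc,
    if (is.na(x$fold_enrichment)) "undefined"
    else format(x$fold_enrichment, digits = 4),
    if (x$pass) "PASS" else paste("FAIL:", x$reason)))
  invisible(x)
}

#' Per-sample library QC summary
#'
#' One row per sample: total fragments, duplicate rate (from
#' [deduplicate()]), unique-read rate, fraction of unique fragments
#' overlapping a gene body, and the spike-in pass flag.
#'
#' @param fragment_list named list of per-sample fragment data frames.
#' @param genes gene models for the gene-body fraction.
#' @param spikein_reports optional named list of
#'   [spikein_enrichment()] reports, one per sample.
#' @return data frame: sample_id, n_fragments, duplicate_rate,
#'   unique_rate, genebody_fraction, spikein_pass.
#' @export
library_summary <- function(fragment_list, genes, spikein_reports = NULL) {
  rows <- lapply(names(fragment_list), function(s) {
    fr <- fragment_list[[s]]
    dd <- deduplicate(fr)
    gb <- if (nrow(dd$fragments) == 0L) NA_real_ else
      mean(count_fragment_hits(dd$fragments, genes))
    data.frame(sample_id = s, n_fragments = nrow(fr),
               duplicate_rate = dd$duplicate_rate,
               unique_rate = 1 - dd$duplicate_rate,
               genebody_fraction = gb,
               spikein_pass = if (is.null(spikein_reports)) NA
                              else spikein_reports[[s]]$pass,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# per-fragment indicator of >=1 bp overlap with any gene body
count_fragment_hits <- function(fragments, genes) {
  # disjoint chromosome sets are a legitimate zero-overlap case
  hits <- suppressWarnings(GenomicRanges::countOverlaps(
    as_granges0(fragments, "fragment"), as_granges0(genes, "gene"),
    ignore.strand = TRUE))
  hits > 0L
}
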