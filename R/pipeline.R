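#' Configuration for an end-to-end pipeline run
#'
#' @param outdir run directory (created if absent).
#' @param seed integer seed forwarded to every stochastic stage.
#' @param simulation a [simulation_config()]; its seed is overridden by
#'   `seed`. Ignored when `counts` and `sample_sheet` are supplied.
#' @param counts,sample_sheet optional pre-computed inputs (gene x
#'   sample matrix and the matching sheet) replacing the simulate
#'   stage.
#' @param sets optional named list of gene sets to score; defaults to
#'   the simulated cohort's target sets.
#' @param min_median gene filter threshold (median raw count >= 8).
#' @param fdr_cutoff DMG FDR cutoff (strict `<`, default 0.1).
#' @param pseudocount activity-score pseudocount (default 1).
#' @param k number of epigenomic groups (default 3).
#' @param min_fold spike-in pass threshold (default 100).
#' @param capture_efficiency,background_rate spike-in simulation rates
#'   used for the QC stage of synthetic runs.
#' @param cluster toggle the clustering stage; when off, survival and
#'   dynamics fall back to the clinical progressed / non-progressed
#'   strata.
#' @param write_matrices also write the normalized and stabilized
#'   matrices (large TSVs; off by default).
#' @param plots write KM, waterfall and PCA plots as PNG.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(outdir,
                            seed = 1L,
                            simulation = simulation_config(seed = seed),
                            counts = NULL, sample_sheet = NULL,
                            sets = NULL,
                            min_median = 8, fdr_cutoff = 0.1,
                            pseudocount = 1, k = 3L, min_fold = 100,
                            capture_efficiency = 0.5,
                            background_rate = 0.004,
                            cluster = TRUE,
                            write_matrices = FALSE, plots = FALSE) {
  stopifnot(min_median >= 0, fdr_cutoff > 0, fdr_cutoff <= 1,
            pseudocount >= 0, k >= 1L, min_fold > 0)
  simulation$seed <- as.integer(seed)
  structure(list(outdir = outdir, seed = as.integer(seed),
                 simulation = simulation, counts = counts,
                 sample_sheet = sample_sheet, sets = sets,
                 min_median = min_median, fdr_cutoff = fdr_cutoff,
                 pseudocount = pseudocount, k = as.integer(k),
                 min_fold = min_fold,
                 capture_efficiency = capture_efficiency,
                 background_rate = background_rate,
                 cluster = isTRUE(cluster),
                 write_matrices = isTRUE(write_matrices),
                 plots = isTRUE(plots)),
            class = "pipeline_config")
}

#' Run the full cfDNA 5hmC analysis pipeline
#'
#' Executes, in order: simulate (unless counts are supplied) -> spike-in
#' QC -> gene filter and median-of-ratios normalization -> differential
#' methylation (baseline, progressed vs non-progressed) -> gene-set
#' over-representation of hypermethylated DMGs -> activity scores
#' against the pooled healthy control -> epigenomic clustering of
#' baseline samples on the DMG profile -> progression-free survival
#' (median-split log-rank, Cox hazard ratio, ANCOVA adjustment) ->
#' longitudinal score dynamics. Every stage writes a TSV into the run
#' directory and logs its parameters; a manifest JSON records the seed,
#' parameters and an MD5 checksum of each output, so a re-run with the
#' same seed is verifiably identical. A stage failure aborts the run
#' naming the stage; earlier outputs are retained.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with every stage's in-memory result plus
#'   `run_dir` and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$outdir, "run.log")
  cat("", file = logfile)
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    cat(msg, "\n", file = logfile, append = TRUE, sep = "")
    message(msg)
  }
  outputs <- character()
  emit <- function(x, name) {
    path <- file.path(config$outdir, name)
    if (is.matrix(x)) write_counts_tsv(x, path) else write_tsv(x, path)
    outputs <<- c(outputs, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  res <- list(run_dir = config$outdir)

  # -- simulate ------------------------------------------------------
  if (is.null(config$counts)) {
    res$cohort <- stage("simulate", simulate_cohort(config$simulation))
    counts <- cohort_count_matrix(res$cohort)
    sheet <- res$cohort$sample_sheet
    sets <- config$sets
    if (is.null(sets))
      sets <- c(res$cohort$truth$target_sets,
                signature_sets(res$cohort))
    truth_path <- file.path(config$outdir, "truth.json")
    jsonlite::write_json(
      list(groups = as.list(res$cohort$truth$groups),
           true_score = as.list(res$cohort$truth$true_score)),
      truth_path, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, truth_path)
    log_line("simulate: %d genes x %d samples, seed %d",
             nrow(counts), ncol(counts), config$seed)
  } else {
    counts <- config$counts
    sheet <- config$sample_sheet
    sets <- config$sets
    if (is.null(sheet) || is.null(sets))
      stop("supplied counts need sample_sheet and sets")
    log_line("simulate: skipped (counts supplied)")
  }
  emit(counts, "counts.tsv")
  emit(sheet, "sample_sheet.tsv")

  # -- spike-in QC ---------------------------------------------------
  res$qc <- stage("qc", {
    ids <- sheet$sample_id
    reports <- lapply(seq_along(ids), function(i)
      spikein_enrichment(simulate_spikein(
        2e5, 2e5, config$capture_efficiency, config$background_rate,
        seed = config$seed + i), min_fold = config$min_fold))
    names(reports) <- ids
    data.frame(sample_id = ids,
               reads_hmc = vapply(reports, `[[`, 0, "reads_hmc"),
               reads_c = vapply(reports, `[[`, 0, "reads_c"),
               reads_mc = vapply(reports, `[[`, 0, "reads_mc"),
               fold_enrichment =
                 vapply(reports, `[[`, 0, "fold_enrichment"),
               pass = vapply(reports, `[[`, TRUE, "pass"),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  emit(res$qc, "qc_spikein.tsv")
  log_line("qc: %d/%d libraries pass >= %g-fold spike-in enrichment",
           sum(res$qc$pass), nrow(res$qc), config$min_fold)

  # -- filter + normalize -------------------------------------------
  res$filtered <- stage("normalize", filter_genes(counts,
                                                  config$min_median))
  res$size_factors <- stage("normalize", size_factors(res$filtered))
  res$normalized <- normalize_counts(res$filtered, res$size_factors)
  res$stabilized <- stabilize(res$normalized)
  emit(data.frame(sample_id = names(res$size_factors),
                  size_factor = res$size_factors), "size_factors.tsv")
  if (config$write_matrices) {
    emit(round(res$normalized, 4), "normalized.tsv")
    emit(round(res$stabilized, 4), "stabilized.tsv")
  }
  log_line("normalize: %d/%d genes kept (median >= %g)",
           nrow(res$filtered), nrow(counts), config$min_median)

  # -- differential methylation (baseline, progressed vs not) -------
  base_ids <- sheet$sample_id[sheet$type == "patient" &
                              sheet$timepoint == sheet$timepoint[1L]]
  base_tp <- unique(sheet$timepoint[sheet$sample_id %in% base_ids])[1L]
  prog <- sheet$event[match(base_ids, sheet$sample_id)]
  res$dmg <- stage("diffmeth", {
    lab <- factor(ifelse(prog == 1, "progressed", "nonprogressed"),
                  levels = c("nonprogressed", "progressed"))
    nb_wald_test(res$filtered[, base_ids], res$size_factors[base_ids],
                 lab, fdr_cutoff = config$fdr_cutoff)
  })
  calls <- call_dmgs(res$dmg, config$fdr_cutoff)
  emit(res$dmg, "dmg_table.tsv")
  log_line("diffmeth: %d DMGs (FDR < %g): %d hyper, %d hypo",
           length(calls$hyper) + length(calls$hypo), config$fdr_cutoff,
           length(calls$hyper), length(calls$hypo))

  # -- gene-set enrichment ------------------------------------------
  res$enrichment <- stage("enrich", {
    query <- if (length(calls$hyper)) calls$hyper else
      res$dmg$gene_id[order(res$dmg$p)][1:50]
    hypergeom_enrich(query, sets, rownames(res$filtered))
  })
  emit(res$enrichment, "enrichment.tsv")
  log_line("enrich: top set '%s' (FDR %.3g)", res$enrichment$set[1L],
           res$enrichment$fdr[1L])

  # -- activity scores ----------------------------------------------
  ctrl_ids <- sheet$sample_id[sheet$type == "control"]
  res$control <- stage("score", pooled_control(res$normalized, ctrl_ids))
  pat_ids <- sheet$sample_id[sheet$type == "patient"]
  res$scores <- stage("score",
    score_matrix(res$normalized, res$control, sets, pat_ids,
                 pseudocount = config$pseudocount))
  emit(res$scores, "activity_scores.tsv")
  log_line("score: %d samples x %d sets", length(pat_ids), length(sets))

  # -- clustering ----------------------------------------------------
  anchor_set <- names(sets)[1L]
  base_scores <- res$scores[res$scores$set == anchor_set &
                            res$scores$sample_id %in% base_ids, ]
  anchor <- stats::setNames(base_scores$score, base_scores$sample_id)
  if (config$cluster) {
    res$epigroups <- stage("cluster", {
      dmg_genes <- c(calls$hyper, calls$hypo)
      if (length(dmg_genes) < 2L)
        dmg_genes <- res$dmg$gene_id[order(res$dmg$p)][1:500]
      cluster_samples(res$stabilized[dmg_genes, base_ids, drop = FALSE],
                      k = config$k, anchor_scores = anchor)
    })
    strata_lab <- paste0("EpiGroup", res$epigroups$labels)
    names(strata_lab) <- names(res$epigroups$labels)
    emit(data.frame(sample_id = names(res$epigroups$labels),
                    subject_id = sheet$subject_id[
                      match(names(res$epigroups$labels), sheet$sample_id)],
                    epigroup = strata_lab), "epigroups.tsv")
    emit(data.frame(sample_id = rownames(res$epigroups$pca),
                    res$epigroups$pca[, 1:2]), "pca.tsv")
    log_line("cluster: k = %d, sizes %s", config$k,
             paste(table(res$epigroups$labels), collapse = "/"))
  } else {
    strata_lab <- stats::setNames(
      ifelse(prog == 1, "progressed", "nonprogressed"), base_ids)
    log_line("cluster: skipped; clinical strata used downstream")
  }

  # -- survival ------------------------------------------------------
  res$survival <- stage("survival", {
    sub <- sheet[match(base_ids, sheet$sample_id), ]
    split_lab <- dichotomize_by_median(anchor)
    d <- data.frame(subject_id = sub$subject_id,
                    time_months = sub$time_months, event = sub$event,
                    stratum = split_lab[base_ids],
                    psa_baseline = sub$psa_baseline,
                    ctdna_fraction = sub$ctdna_fraction,
                    epigroup = strata_lab[base_ids],
                    stringsAsFactors = FALSE)
    lr <- logrank_test(d$time_months, d$event, d$stratum)
    cx <- cox_fit(d$time_months, d$event,
                  factor(d$stratum, levels = c("low", "high")))
    km <- lapply(split(d, d$stratum), function(s)
      km_estimate(s$time_months, s$event))
    an <- ancova_adjust(anchor[base_ids], d$stratum,
                        d[, c("psa_baseline", "ctdna_fraction")])
    list(data = d, logrank = lr, cox = cx, km = km, ancova = an)
  })
  emit(res$survival$data, "survival.tsv")
  emit(do.call(rbind, lapply(names(res$survival$km), function(s)
    cbind(stratum = s, as.data.frame(res$survival$km[[s]])))),
    "km_curves.tsv")
  emit(data.frame(
    test = c("logrank", "cox_wald", "ancova_group"),
    statistic = c(res$survival$logrank$chi2, res$survival$cox$z,
                  res$survival$ancova$F),
    estimate = c(NA, res$survival$cox$hr, NA),
    p = c(res$survival$logrank$p, res$survival$cox$p,
          res$survival$ancova$p)), "survival_tests.tsv")
  log_line("survival: log-rank p = %.4g, HR = %.2f (p = %.4g)",
           res$survival$logrank$p, res$survival$cox$hr,
           res$survival$cox$p)

  # -- dynamics ------------------------------------------------------
  res$dynamics <- stage("dynamics", {
    subj_group <- stats::setNames(
      strata_lab[base_ids],
      sheet$subject_id[match(base_ids, sheet$sample_id)])
    dynamics_report(res$scores, sheet, subj_group)
  })
  emit(res$dynamics, "dynamics.tsv")
  log_line("dynamics: %d paired contrasts", nrow(res$dynamics))

  if (config$plots) render_plots(res, config)

  manifest <- list(
    package = "cfhmc",
    version = as.character(utils::packageVersion("cfhmc")),
    seed = config$seed,
    parameters = config[c("min_median", "fdr_cutoff", "pseudocount",
                          "k", "min_fold")],
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest,
                       file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  log_line("done: %d outputs in %s", length(outputs), config$outdir)
  invisible(res)
}

#' Longitudinal activity-score dynamics
#'
#' For each (group, gene set) and each adjacent timepoint pair, a
#' paired t-test of per-subject scores (or Welch when `paired = FALSE`).
#' Subjects missing one timepoint of a pair are excluded from that pair
#' with a warning. Significance stars: `**` for p < 0.0001, `*` for
#' p < 0.05.
#'
#' @param scores score table from [score_matrix()].
#' @param sample_sheet sheet mapping sample_id to subject_id and
#'   timepoint.
#' @param groups named vector mapping subject_id to group label.
#' @param paired use the paired test (default) or Welch.
#' @return data frame: group, set, contrast, n_pairs, mean_diff
#'   (later minus earlier timepoint), p, stars.
#' @export
dynamics_report <- function(scores, sample_sheet, groups, paired = TRUE) {
  sheet <- sample_sheet[sample_sheet$type == "patient", ]
  tps <- unique(sheet$timepoint)
  if (length(tps) < 2L) stop("need at least two timepoints")
  m <- match(scores$sample_id, sheet$sample_id)
  scores <- scores[!is.na(m), ]
  scores$subject <- sheet$subject_id[m[!is.na(m)]]
  scores$timepoint <- sheet$timepoint[m[!is.na(m)]]
  rows <- list()
  for (g in sort(unique(groups))) {
    subj <- names(groups)[groups == g]
    for (nm in sort(unique(scores$set))) {
      d <- scores[scores$set == nm & scores$subject %in% subj, ]
      wide <- stats::reshape(
        d[, c("subject", "timepoint", "score")],
        idvar = "subject", timevar = "timepoint", direction = "wide")
      for (i in seq_len(length(tps) - 1L)) {
        a <- wide[[paste0("score.", tps[i])]]
        b <- wide[[paste0("score.", tps[i + 1L])]]
        ok <- !is.na(a) & !is.na(b)
        if (sum(!ok))
          warning(sum(!ok), " subject(s) missing a timepoint for ",
                  tps[i], " vs ", tps[i + 1L], "; excluded")
        if (sum(ok) < 2L) next
        p <- if (paired) paired_p(a[ok], b[ok]) else
          welch_p(a[ok], b[ok])
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, set = nm,
          contrast = paste(tps[i], "vs", tps[i + 1L]),
          n_pairs = sum(ok), mean_diff = mean(b[ok] - a[ok]), p = p,
          stars = if (p < 1e-4) "**" else if (p < 0.05) "*" else "",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# paired t with the degenerate conventions used across the package
paired_p <- function(x, y) {
  d <- y - x
  s <- stats::sd(d)
  if (s == 0) return(if (mean(d) == 0) 1 else 0)
  t <- mean(d) / (s / sqrt(length(d)))
  2 * stats::pt(-abs(t), length(d) - 1L)
}
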