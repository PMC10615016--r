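#' Configuration for a synthetic cfDNA 5hmC cohort
#'
#' Builds and validates the parameter object consumed by
#' [simulate_cohort()]. Defaults mirror the study design the package
#' models: 55 advanced prostate-cancer patients sampled at ADT start
#' (baseline), after 3 months of therapy, and at progression or at the
#' 24-month visit; 7 healthy plasma controls; three latent epigenomic
#' subgroups (6/31/18), each with its own stable genome-wide 5hmC
#' signature, of which EpiGroup 1 additionally carries elevated 5hmC in
#' an androgen-response-like gene set at baseline, loses it under
#' therapy, and regains it at progression.
#'
#' @param seed integer seed; the same config and seed reproduce the
#'   cohort byte-for-byte.
#' @param n_genes number of genes.
#' @param n_controls number of healthy control samples (default 7; the
#'   activity score pools "the 7 healthy controls").
#' @param group_sizes integer vector of patients per EpiGroup 1..3.
#' @param timepoints ordered timepoint labels.
#' @param baseline_mu per-gene negative-binomial mean in reads. A
#'   scalar is recycled; `NULL` draws log-normal means
#'   (meanlog = log(300), sdlog = 1) from `seed` — gene-body means of a
#'   few hundred reads, consistent with ~18M reads per library over
#'   ~20k genes.
#' @param dispersion per-gene NB dispersion alpha with
#'   Var = mu + alpha * mu^2; 0 is the Poisson limit. The default 0.05
#'   (cross-patient CV ~22%) reproduces realistic within-group
#'   activity-score spread.
#' @param libsize_factors per-sample positive library-size multipliers;
#'   `NULL` draws log-normal(0, 0.15) factors from `seed`.
#' @param effect_log2fc data frame with columns `set`, `group`,
#'   `timepoint`, `log2fc`: additive log2 shifts applied to the named
#'   target set in the named EpiGroup at the named timepoint. `NULL`
#'   gives the default trajectory: androgen set +0.25 at baseline,
#'   0 at month 3, +0.3 at the endpoint in EpiGroup 1; immune set
#'   -0.2 at baseline and endpoint in EpiGroup 1. A zero-row data frame
#'   means no set-level effects.
#' @param target_sets named list of gene index vectors designating the
#'   androgen-response-like and immune-like sets; `NULL` uses the first
#'   97 genes ("androgen_response") and the next 200
#'   ("immune_response"). The first set anchors the true activity score
#'   and the hazard model.
#' @param patient_effect_sd SD, in activity-score units (100 x log2),
#'   of each patient's random activation of each target set, constant
#'   across timepoints. Default 4.
#' @param signature_genes_per_group number of genes in each EpiGroup's
#'   private stable signature (disjoint across groups and from the
#'   target sets; default 3000). Set 0 to disable.
#' @param signature_sd SD (log2) of the signature shifts (default
#'   0.75).
#' @param hazard_base baseline progression hazard, events/month.
#' @param hazard_beta log-hazard increment per unit of true baseline
#'   activity score. `NULL` (default) calibrates it so the median-score
#'   split a downstream analyst forms (true score plus the count-model
#'   measurement noise) separates strata whose true hazards differ by
#'   `hazard_target_hr`.
#' @param hazard_target_hr target true hazard ratio across the
#'   median-score split used when `hazard_beta` is `NULL` (default 3).
#' @param censor_horizon administrative censoring time in months.
#' @param fragment_length cfDNA fragment length in bp used by
#'   [simulate_fragments()] (nucleosomal 167 bp).
#'
#' @return A validated list of class `"simulation_config"`.
#' @seealso [simulate_cohort()]
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 20000L,
                              n_controls = 7L,
                              group_sizes = c(6L, 31L, 18L),
                              timepoints = c("baseline", "month3", "endpoint"),
                              baseline_mu = NULL,
                              dispersion = 0.05,
                              libsize_factors = NULL,
                              effect_log2fc = NULL,
                              target_sets = NULL,
                              patient_effect_sd = 4,
                              signature_genes_per_group = 3000L,
                              signature_sd = 0.75,
                              hazard_base = 0.015,
                              hazard_beta = NULL,
                              hazard_target_hr = 3,
                              censor_horizon = 24,
                              fragment_length = 167L) {
  if (length(group_sizes) < 1L || any(group_sizes < 1L))
    stop("all group sizes must be >= 1")
  if (censor_horizon <= 0) stop("censor_horizon must be > 0")
  if (n_controls < 1L) stop("need at least one control sample")
  if (!is.null(baseline_mu) && any(baseline_mu <= 0))
    stop("configuration error: all baseline_mu must be > 0")
  if (any(dispersion < 0)) stop("dispersion alpha must be >= 0")
  if (!is.null(libsize_factors) && any(libsize_factors <= 0))
    stop("libsize_factors must be positive")
  if (hazard_base <= 0) stop("hazard_base must be > 0")
  if (patient_effect_sd < 0 || signature_sd < 0)
    stop("standard deviations must be >= 0")
  if (!is.null(target_sets)) {
    if (is.null(names(target_sets)) || any(!nzchar(names(target_sets))))
      stop("target_sets must be a named list")
    if (any(vapply(target_sets, length, 0L) == 0L))
      stop("configuration error: empty target gene set")
    if (any(unlist(target_sets) > n_genes))
      stop("target set index exceeds n_genes")
  }
  if (!is.null(effect_log2fc)) {
    need <- c("set", "group", "timepoint", "log2fc")
    if (!all(need %in% names(effect_log2fc)))
      stop("effect_log2fc needs columns: ", paste(need, collapse = ", "))
  }
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_controls = as.integer(n_controls),
    group_sizes = as.integer(group_sizes),
    timepoints = timepoints, baseline_mu = baseline_mu,
    dispersion = dispersion, libsize_factors = libsize_factors,
    effect_log2fc = effect_log2fc, target_sets = target_sets,
    patient_effect_sd = patient_effect_sd,
    signature_genes_per_group = as.integer(signature_genes_per_group),
    signature_sd = signature_sd,
    hazard_base = hazard_base, hazard_beta = hazard_beta,
    hazard_target_hr = hazard_target_hr,
    censor_horizon = censor_horizon,
    fragment_length = as.integer(fragment_length)
  ), class = "simulation_config")
}

default_effects <- function(timepoints) {
  tp <- timepoints
  data.frame(
    set = c(rep("androgen_response", 3L), "immune_response", "immune_response"),
    group = "EpiGroup1",
    timepoint = c(tp[1L], tp[min(2L, length(tp))],
                  tp[min(3L, length(tp))], tp[1L],
                  tp[min(3L, length(tp))]),
    log2fc = c(0.25, 0, 0.3, -0.2, -0.2),
    stringsAsFactors = FALSE
  )[seq_len(if (length(timepoints) >= 3L) 5L else 1L), , drop = FALSE]
}

#' Simulate a complete synthetic cfDNA 5hmC cohort
#'
#' Draws negative-binomial gene-body counts for patients at each
#' timepoint and for healthy controls (controls appear once, at a
#' baseline pseudo-timepoint), then generates progression-free survival
#' outcomes. Counts are
#' `NB(mean = libsize * mu * 2^shift, dispersion = alpha)` with
#' `Var = mu + alpha * mu^2`; `alpha = 0` draws Poisson counts. The
#' per-gene log2 shift of a patient sample is the sum of
#' \itemize{
#'   \item the EpiGroup's stable signature (zero for controls),
#'   \item the configured (set, group, timepoint) effects, and
#'   \item the patient's own random target-set activation
#'     (`N(0, patient_effect_sd / 100)` per set, constant over time).
#' }
#' A patient's true baseline activity score is 100 times their mean
#' shift over the first target set at the first timepoint. Event times
#' are exponential with
#' `rate = hazard_base * exp(hazard_beta * true_score)`, censored at
#' `censor_horizon`; a `NULL` `hazard_beta` is calibrated on the
#' realized true scores so the median-split true hazard ratio equals
#' `hazard_target_hr`.
#'
#' @param config a [simulation_config()] object.
#' @return A list of class `"synthetic_cohort"`:
#'   \describe{
#'     \item{counts}{named list of integer gene x sample matrices, one
#'       per timepoint; control columns sit in the first timepoint's
#'       matrix.}
#'     \item{sample_sheet}{data frame of sample_id, subject_id, type,
#'       timepoint, covariates (baseline PSA ng/ml, ctDNA fraction) and
#'       survival fields (time_months, event) repeated per sample.}
#'     \item{truth}{latent state: EpiGroup labels, true per-subject
#'       baseline scores, uncensored event times, target sets, the
#'       effect table, signature shifts, the hazard_beta used, per-gene
#'       means and per-sample library sizes.}
#'   }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  gene_ids <- sprintf("gene%05d", seq_len(ng))

  mu <- config$baseline_mu
  if (is.null(mu)) mu <- stats::rlnorm(ng, meanlog = log(300), sdlog = 1)
  mu <- rep_len(mu, ng)
  if (any(mu <= 0)) stop("configuration error: non-positive gene mean")
  alpha <- rep_len(config$dispersion, ng)

  sets <- config$target_sets
  if (is.null(sets)) {
    if (ng < 297L) stop("default target sets need n_genes >= 297")
    sets <- list(androgen_response = 1:97, immune_response = 98:297)
  }
  if (any(vapply(sets, length, 0L) == 0L))
    stop("configuration error: empty target gene set")
  effects <- config$effect_log2fc
  if (is.null(effects)) effects <- default_effects(config$timepoints)

  groups <- rep(paste0("EpiGroup", seq_along(config$group_sizes)),
                config$group_sizes)
  n_pat <- length(groups)
  subjects <- sprintf("S%02d", seq_len(n_pat))
  names(groups) <- subjects
  group_names <- unique(groups)
  controls <- sprintf("HC%d", seq_len(config$n_controls))

  n_samp <- n_pat * length(config$timepoints) + config$n_controls
  lf <- config$libsize_factors
  if (is.null(lf)) lf <- stats::rlnorm(n_samp, 0, 0.15)
  lf <- rep_len(lf, n_samp)

  # stable per-group signatures on genes outside the target sets
  signature <- matrix(0, ng, length(group_names),
                      dimnames = list(NULL, group_names))
  n_sig <- config$signature_genes_per_group
  if (n_sig > 0L) {
    free <- setdiff(seq_len(ng), unlist(sets))
    if (length(free) < n_sig * length(group_names))
      stop("not enough genes outside the target sets for ",
           "signature_genes_per_group = ", n_sig,
           "; reduce it or raise n_genes")
    picked <- sample(free, n_sig * length(group_names))
    for (j in seq_along(group_names)) {
      idx <- picked[(j - 1L) * n_sig + seq_len(n_sig)]
      signature[idx, j] <- stats::rnorm(n_sig, 0, config$signature_sd)
    }
  }

  # per-patient random activation of each target set (log2), fixed in time
  eps <- matrix(stats::rnorm(n_pat * length(sets), 0,
                             config$patient_effect_sd / 100),
                n_pat, length(sets),
                dimnames = list(subjects, names(sets)))

  set_effect <- function(set_name, group, tp) {
    rows <- effects$set == set_name & effects$group == group &
      effects$timepoint == tp
    if (any(rows)) sum(effects$log2fc[rows]) else 0
  }
  unknown <- setdiff(effects$set, names(sets))
  if (length(unknown))
    stop("effect references unknown target set: ",
         paste(unknown, collapse = ", "))

  shift_matrix <- function(tp) {
    sh <- signature[, groups, drop = FALSE]
    colnames(sh) <- subjects
    for (s in seq_along(sets)) {
      idx <- sets[[s]]
      per_pat <- vapply(subjects, function(p)
        set_effect(names(sets)[s], groups[[p]], tp) +
          eps[p, s], 0)
      sh[idx, ] <- sh[idx, ] + rep(per_pat, each = length(idx))
    }
    sh
  }

  draw <- function(mean_mat) {
    out <- matrix(0L, nrow(mean_mat), ncol(mean_mat),
                  dimnames = dimnames(mean_mat))
    pois <- alpha == 0
    if (any(pois))
      out[pois, ] <- stats::rpois(sum(pois) * ncol(mean_mat),
                                  lambda = mean_mat[pois, ])
    if (any(!pois))
      out[!pois, ] <- stats::rnbinom(sum(!pois) * ncol(mean_mat),
                                     mu = mean_mat[!pois, ],
                                     size = 1 / alpha[!pois])
    storage.mode(out) <- "integer"
    out
  }

  counts <- list()
  sample_rows <- list()
  idx <- 0L
  base_shift <- NULL
  for (tp in config$timepoints) {
    ids <- paste(subjects, tp, sep = "_")
    f <- lf[idx + seq_len(n_pat)]
    idx <- idx + n_pat
    shifts <- shift_matrix(tp)
    if (is.null(base_shift)) base_shift <- shifts
    mean_mat <- (mu * 2^shifts) * rep(f, each = ng)
    dimnames(mean_mat) <- list(gene_ids, ids)
    counts[[tp]] <- draw(mean_mat)
    sample_rows[[tp]] <- data.frame(
      sample_id = ids, subject_id = subjects, type = "patient",
      timepoint = tp, stringsAsFactors = FALSE)
  }
  fc <- lf[idx + seq_len(config$n_controls)]
  mean_ctrl <- mu %o% fc
  dimnames(mean_ctrl) <- list(gene_ids, controls)
  ctrl_counts <- draw(mean_ctrl)
  counts[[config$timepoints[1L]]] <-
    cbind(counts[[config$timepoints[1L]]], ctrl_counts)
  sample_rows$control <- data.frame(
    sample_id = controls, subject_id = controls, type = "control",
    timepoint = config$timepoints[1L], stringsAsFactors = FALSE)

  # true baseline activity score over the anchor (first) target set
  anchor <- sets[[1L]]
  true_score <- 100 * colMeans(base_shift[anchor, , drop = FALSE] -
                                 signature[anchor, groups, drop = FALSE])
  names(true_score) <- subjects

  # score measurement noise implied by the count model: the downstream
  # analyst stratifies on the *measured* score, so the hazard target is
  # calibrated on that split (true + NB measurement noise), keeping the
  # true hazard ratio between the analyst's strata at hazard_target_hr
  score_noise_sd <- (100 / log(2)) *
    sqrt(mean(1 / mu[anchor] + alpha[anchor]) / length(anchor))
  beta <- config$hazard_beta
  calib <- true_score
  if (is.null(beta)) {
    calib <- true_score + stats::rnorm(n_pat, 0, score_noise_sd)
    hi <- calib > stats::median(calib)
    gap <- mean(true_score[hi]) - mean(true_score[!hi])
    beta <- if (gap > 0) log(config$hazard_target_hr) / gap else 0
  }
  rate <- config$hazard_base * exp(beta * true_score)
  true_time <- stats::rexp(n_pat, rate = rate)
  event <- as.integer(true_time <= config$censor_horizon)
  time_obs <- pmin(true_time, config$censor_horizon)

  psa <- stats::rlnorm(n_pat, meanlog = log(21.5), sdlog = 1.2)
  ctdna <- stats::rbeta(n_pat, 1.5, 8)

  sheet <- do.call(rbind, sample_rows)
  rownames(sheet) <- NULL
  m <- match(sheet$subject_id, subjects)
  sheet$psa_baseline <- psa[m]
  sheet$ctdna_fraction <- ctdna[m]
  sheet$time_months <- time_obs[m]
  sheet$event <- event[m]

  structure(list(
    counts = counts,
    sample_sheet = sheet,
    truth = list(groups = groups, true_score = true_score,
                 true_time = stats::setNames(true_time, subjects),
                 event = stats::setNames(event, subjects),
                 time_months = stats::setNames(time_obs, subjects),
                 target_sets = lapply(sets, function(i) gene_ids[i]),
                 effects = effects, hazard_beta = beta,
                 score_noise_sd = score_noise_sd,
                 calibration_scores = stats::setNames(calib, subjects),
                 signature = signature, patient_effects = eps,
                 mu = stats::setNames(mu, gene_ids), libsize = lf)
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  sheet <- x$sample_sheet
  cat("synthetic cfDNA 5hmC cohort\n")
  cat(sprintf("  %d genes, %d samples (%d patients x %d timepoints + %d controls)\n",
              nrow(x$counts[[1L]]), nrow(sheet),
              length(x$truth$groups), length(x$counts),
              sum(sheet$type == "control")))
  cat(sprintf("  EpiGroups: %s\n",
              paste(names(table(x$truth$groups)),
                    table(x$truth$groups), sep = "=", collapse = ", ")))
  cat(sprintf("  progressed: %d of %d (hazard_beta = %.4f)\n",
              sum(x$truth$event), length(x$truth$event),
              x$truth$hazard_beta))
  invisible(x)
}

#' Gene sets derived from a synthetic cohort's group signatures
#'
#' Each EpiGroup's stable signature is split by direction into an
#' `<group>_up` and `<group>_down` gene set. Differential methylation
#' between a group and the rest should over-represent these sets, so
#' they give the enrichment stage a ground-truth positive control.
#'
#' @param cohort a `synthetic_cohort`.
#' @return named list of gene-id vectors (empty sets dropped).
#' @export
signature_sets <- function(cohort) {
  sig <- cohort$truth$signature
  gene_ids <- names(cohort$truth$mu)
  out <- list()
  for (g in colnames(sig)) {
    out[[paste0(g, "_up")]] <- gene_ids[sig[, g] > 0]
    out[[paste0(g, "_down")]] <- gene_ids[sig[, g] < 0]
  }
  out[vapply(out, length, 0L) > 0L]
}

#' Combine a cohort's per-timepoint counts into one matrix
#'
#' @param cohort a `synthetic_cohort`.
#' @return integer matrix, genes x all samples (ids unique across
#'   timepoints).
#' @export
cohort_count_matrix <- function(cohort) {
  do.call(cbind, unname(cohort$counts))
}

#' Place synthetic cfDNA fragments inside gene bodies
#'
#' For each gene, places exactly the requested number of fixed-length
#' fragments uniformly at random, fully inside the gene body.
#' Coordinates are BED-style 0-based half-open.
#'
#' @param gene_models data frame with columns gene_id, chrom, start,
#'   end (0-based half-open) and optionally strand.
#' @param counts_column non-negative integer fragment count per gene,
#'   parallel to `gene_models` rows.
#' @param seed integer seed.
#' @param fragment_length fragment length in bp (default 167).
#' @return BED6-style data frame (chrom, start, end, name, score,
#'   strand); zero rows when all counts are zero.
#' @export
simulate_fragments <- function(gene_models, counts_column, seed,
                               fragment_length = 167L) {
  stopifnot(length(counts_column) == nrow(gene_models))
  widths <- gene_models$end - gene_models$start
  bad <- widths < fragment_length
  if (any(bad))
    stop("gene(s) shorter than fragment length: ",
         paste(gene_models$gene_id[bad], collapse = ", "))
  set.seed(seed)
  n <- sum(counts_column)
  if (n == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  g <- rep(seq_len(nrow(gene_models)), counts_column)
  lo <- gene_models$start[g]
  hi <- gene_models$end[g] - fragment_length      # inclusive max start
  start <- lo + floor(stats::runif(n) * (hi - lo + 1L))
  start <- pmin(start, hi)                        # guard runif(1) == 1
  data.frame(
    chrom = gene_models$chrom[g],
    start = as.integer(start),
    end = as.integer(start + fragment_length),
    name = paste0("frag", seq_len(n)),
    score = 0L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

#' Simulate spike-in amplicon capture
#'
#' Models the C / 5mC / 5hmC lambda-amplicon spike-in pool added before
#' 5hmC capture: reads from the 5hmC class are captured with
#' `capture_efficiency`, reads from the unmodified C and 5mC classes
#' leak through at `background_rate`. Captured reads per class are
#' binomial draws over input copies.
#'
#' @param copies_hmc,copies_c input copies of the 5hmC class and of
#'   each unmodified class (C and 5mC).
#' @param capture_efficiency probability a 5hmC copy is captured.
#' @param background_rate probability an unmodified copy is captured.
#' @param seed integer seed.
#' @return data frame with columns class ("C", "mC", "hmC"), copies,
#'   reads — the input table for [spikein_enrichment()].
#' @export
simulate_spikein <- function(copies_hmc, copies_c, capture_efficiency,
                             background_rate, seed) {
  if (capture_efficiency < 0 || capture_efficiency > 1 ||
      background_rate < 0 || background_rate > 1)
    stop("rates must be in [0, 1]")
  set.seed(seed)
  data.frame(
    class = c("C", "mC", "hmC"),
    copies = c(copies_c, copies_c, copies_hmc),
    reads = c(stats::rbinom(2L, copies_c, background_rate),
              stats::rbinom(1L, copies_hmc, capture_efficiency)),
    stringsAsFactors = FALSE)
}
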