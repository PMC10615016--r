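#' Pooled healthy-control profile
#'
#' Per-gene arithmetic mean of normalized counts over the healthy
#' control samples — the denominator profile of the activity score.
#'
#' @param normalized normalized gene x sample matrix.
#' @param control_sample_ids column names of the control samples.
#' @return named numeric vector, one mean per gene.
#' @export
pooled_control <- function(normalized, control_sample_ids) {
  missing <- setdiff(control_sample_ids, colnames(normalized))
  if (length(missing))
    stop("control sample(s) not in matrix: ",
         paste(missing, collapse = ", "))
  if (length(control_sample_ids) < 1L)
    stop("need at least one control sample")
  rowMeans(normalized[, control_sample_ids, drop = FALSE])
}

#' Gene-set activity score for one sample
#'
#' The score is 100 times the mean, over the genes of a set, of the
#' log2 ratio between the patient's normalized count and the pooled
#' healthy-control normalized count:
#' `100 * mean(log2(RC_P + pc) - log2(RC_C + pc))`. It is near zero
#' when the set's 5hmC level matches healthy controls and positive when
#' the set is hypermethylated (activated). Genes missing from either
#' side are dropped with a warning rather than zero-filled. The default
#' pseudocount 1 guards zero counts; `pseudocount = 0` evaluates the
#' bare formula and errors on zero counts.
#'
#' @param patient_col named vector of the sample's normalized counts.
#' @param control pooled control profile from [pooled_control()].
#' @param set character vector of gene ids (one gene set).
#' @param set_name label used in messages.
#' @param pseudocount non-negative offset inside both logs (default 1).
#' @return one-row data frame: score, n_genes_used.
#' @export
activity_score <- function(patient_col, control, set,
                           set_name = "gene set", pseudocount = 1) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  used <- set[set %in% names(patient_col) & set %in% names(control)]
  if (length(used) == 0L)
    stop("no gene of set '", set_name,
         "' is present in both patient and control profiles")
  if (length(used) < length(set))
    warning(length(set) - length(used), " gene(s) of set '", set_name,
            "' missing from the matrix; dropped")
  p <- patient_col[used] + pseudocount
  c0 <- control[used] + pseudocount
  if (pseudocount == 0 && (any(p == 0) || any(c0 == 0)))
    stop("zero normalized count with pseudocount 0 in set '",
         set_name, "'")
  data.frame(score = 100 * mean(log2(p) - log2(c0)),
             n_genes_used = length(used))
}

#' Activity scores for all samples and gene sets
#'
#' @param normalized normalized gene x sample matrix.
#' @param control pooled control profile from [pooled_control()].
#' @param sets named list of gene sets.
#' @param sample_ids columns to score (default: all).
#' @param pseudocount as in [activity_score()].
#' @return data frame (sample_id, set, score, n_genes_used), ordered by
#'   sample then set.
#' @export
score_matrix <- function(normalized, control, sets,
                         sample_ids = colnames(normalized),
                         pseudocount = 1) {
  sample_ids <- sort(sample_ids)
  set_names <- sort(names(sets))
  rows <- lapply(sample_ids, function(s) {
    col <- normalized[, s]
    names(col) <- rownames(normalized)
    do.call(rbind, lapply(set_names, function(nm) {
      r <- activity_score(col, control, sets[[nm]], nm, pseudocount)
      cbind(data.frame(sample_id = s, set = nm,
                       stringsAsFactors = FALSE), r)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare activity scores between groups
#'
#' Per-group mean and SD of the score for each gene set, plus Welch
#' t-test p-values for every pairwise group contrast. Singleton groups
#' have no SD and their contrasts are skipped with a warning.
#'
#' @param table score table from [score_matrix()].
#' @param grouping named vector mapping sample_id to group label.
#' @return list with `summary` (set, group, n, mean, sd) and
#'   `contrasts` (set, group1, group2, mean_diff, p).
#' @export
compare_scores <- function(table, grouping) {
  miss <- setdiff(table$sample_id, names(grouping))
  if (length(miss))
    stop("no group for sample(s): ", paste(miss, collapse = ", "))
  table$group <- grouping[table$sample_id]
  groups <- sort(unique(table$group))
  if (length(groups) < 2L) stop("need at least two groups")

  summary <- do.call(rbind, lapply(split(table, table[c("set", "group")]),
    function(d) data.frame(set = d$set[1L], group = d$group[1L],
                           n = nrow(d), mean = mean(d$score),
                           sd = if (nrow(d) > 1L) stats::sd(d$score)
                                else NA_real_,
                           stringsAsFactors = FALSE)))
  summary <- summary[order(summary$set, summary$group), ]
  rownames(summary) <- NULL

  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  contrasts <- do.call(rbind, unlist(recursive = FALSE,
    lapply(sort(unique(table$set)), function(nm) lapply(pairs, function(pr) {
      x <- table$score[table$set == nm & table$group == pr[1L]]
      y <- table$score[table$set == nm & table$group == pr[2L]]
      if (length(x) < 2L || length(y) < 2L) {
        warning("singleton group in contrast ", pr[1L], " vs ", pr[2L],
                "; skipped")
        return(NULL)
      }
      p <- welch_p(x, y)
      data.frame(set = nm, group1 = pr[1L], group2 = pr[2L],
                 mean_diff = mean(y) - mean(x), p = p,
                 stringsAsFactors = FALSE)
    }))))
  rownames(contrasts) <- NULL
  list(summary = summary, contrasts = contrasts)
}

# two-sample Welch p with the package's degenerate-variance conventions
welch_p <- function(x, y) {
  w1 <- stats::var(x) / length(x)
  w2 <- stats::var(y) / length(y)
  se <- sqrt(w1 + w2)
  if (se == 0) return(if (mean(x) == mean(y)) 1 else 0)
  t <- (mean(y) - mean(x)) / se
  df <- (w1 + w2)^2 / (w1^2 / (length(x) - 1L) + w2^2 / (length(y) - 1L))
  2 * stats::pt(-abs(t), df)
}
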