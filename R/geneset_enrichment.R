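#' Read a GMT gene-set collection
#'
#' One set per line: name TAB description TAB gene ids. Duplicate genes
#' within a line are dropped with a warning.
#'
#' @param path GMT file.
#' @return named list of character vectors of gene ids.
#' @export
load_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("GMT parse error at line ", i, ": fewer than 3 fields")
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate gene ids in set '", fields[1L],
              "' (line ", i, "); de-duplicated")
      genes <- unique(genes)
    }
    sets[[fields[1L]]] <- genes
  }
  sets
}

#' Write a gene-set collection as GMT
#' @param sets named list of gene-id vectors.
#' @param path output file.
#' @param descriptions optional per-set description strings.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    ""), path)
  invisible(path)
}

#' Hypergeometric over-representation of gene sets in a query list
#'
#' Tests each gene set for over-representation in a query gene list
#' (typically hyper- or hypomethylated DMGs) against a gene universe
#' (typically the filtered gene list). The p-value is the exact
#' hypergeometric upper tail P(X >= k) with N = |universe|,
#' K = |set within universe|, n = |query|; BH correction is applied
#' across the tested sets. Sets with no gene in the universe are
#' skipped.
#'
#' @param query character vector of query gene ids (subset of
#'   `universe`).
#' @param sets named list of gene sets.
#' @param universe character vector of background gene ids.
#' @return data frame: set, k (overlap), K (set size in universe),
#'   n (query size), N (universe size), p, fdr; ordered by p.
#' @export
hypergeom_enrich <- function(query, sets, universe) {
  universe <- unique(universe)
  query <- unique(query)
  off <- setdiff(query, universe)
  if (length(off))
    stop("query gene(s) absent from universe: ",
         paste(utils::head(off, 5L), collapse = ", "),
         if (length(off) > 5L) " ..." else "")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    set_in <- intersect(sets[[nm]], universe)
    K <- length(set_in)
    if (K == 0L) return(NULL)
    k <- length(intersect(set_in, query))
    # upper tail including k: P(X >= k); floored so p stays > 0 even
    # when the tail underflows double precision
    p <- max(stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE),
             .Machine$double.xmin)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      fdr = numeric(), stringsAsFactors = FALSE))
  out$fdr <- bh_fdr(out$p)
  out[order(out$p), , drop = FALSE]
}
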