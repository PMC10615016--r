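#' Unsupervised epigenomic subgrouping of samples
#'
#' Clusters samples on a variance-stabilized matrix (typically
#' restricted to DMGs): genes are z-scored across samples, pairwise
#' Euclidean distances feed Ward-linkage hierarchical clustering, and
#' the tree is cut at `k` groups. When per-sample anchor scores are
#' supplied (the androgen-set activity score), labels are renumbered by
#' descending mean score so group 1 is the high-score group; otherwise
#' the tree-cut labels are kept. A PCA of the same z-scored matrix is
#' attached.
#'
#' @param x transformed gene x sample matrix (>= 2 genes).
#' @param k number of groups (default 3).
#' @param anchor_scores optional named per-sample score used to order
#'   the group labels.
#' @return list of class `"epigroup_result"`: `labels` (named integer
#'   vector 1..k), `hclust` (the merge tree), `pca` (coordinates),
#'   `variance_explained`.
#' @export
cluster_samples <- function(x, k = 3L, anchor_scores = NULL) {
  if (ncol(x) < k) stop("k exceeds the number of samples")
  if (nrow(x) < 2L) stop("need at least 2 genes")
  v <- row_vars(x)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) dropped before z-scoring")
    x <- x[v > 0, , drop = FALSE]
    if (nrow(x) < 2L) stop("fewer than 2 genes left after dropping")
  }
  z <- t(scale(t(x)))
  hc <- stats::hclust(stats::dist(t(z)), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  if (!is.null(anchor_scores) && k > 1L) {
    means <- tapply(anchor_scores[names(labels)], labels, mean)
    remap <- stats::setNames(seq_len(k), names(sort(means,
                                                    decreasing = TRUE)))
    labels <- stats::setNames(as.integer(remap[as.character(labels)]),
                              names(labels))
  }
  p <- pca_samples(z, n_components = min(10L, ncol(z), nrow(z)))
  structure(list(labels = labels, hclust = hc, pca = p$coordinates,
                 variance_explained = p$variance_explained),
            class = "epigroup_result")
}

#' @export
print.epigroup_result <- function(x, ...) {
  cat("epigenomic subgrouping of", length(x$labels), "samples\n")
  print(table(EpiGroup = x$labels))
  cat("PC variance explained:",
      paste0(round(100 * utils::head(x$variance_explained, 3L), 1),
             "%", collapse = ", "), "\n")
  invisible(x)
}

#' Principal component analysis of samples
#'
#' Column-centers the samples-in-columns matrix and extracts components
#' by singular value decomposition. Sign convention: within each
#' component the largest-magnitude gene loading is positive, so results
#' are deterministic across platforms.
#'
#' @param x gene x sample matrix.
#' @param n_components number of components
#'   (<= min(n samples, n genes)).
#' @return list: `coordinates` (samples x components),
#'   `variance_explained` (per kept component, non-increasing),
#'   `loadings` (genes x components).
#' @export
pca_samples <- function(x, n_components = 2L) {
  m <- t(x)                        # samples x genes
  if (n_components > min(dim(m)))
    stop("n_components exceeds min(n_samples, n_genes)")
  m <- scale(m, center = TRUE, scale = FALSE)
  if (all(abs(m) < 1e-12)) stop("constant matrix: no variance")
  sv <- svd(m, nu = n_components, nv = n_components)
  flip <- vapply(seq_len(n_components), function(j) {
    l <- sv$v[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, 0)
  coords <- sweep(sv$u %*% diag(sv$d[seq_len(n_components)],
                                n_components), 2L, flip, "*")
  rownames(coords) <- colnames(x)
  colnames(coords) <- paste0("PC", seq_len(n_components))
  loadings <- sweep(sv$v, 2L, flip, "*")
  rownames(loadings) <- rownames(x)
  colnames(loadings) <- colnames(coords)
  ve <- sv$d^2 / sum(sv$d^2)
  list(coordinates = coords,
       variance_explained = ve[seq_len(n_components)],
       loadings = loadings)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same
#' samples; 1 means identical partitions, 0 the expectation under
#' random labelings.
#'
#' @param a,b label vectors of equal length (any label alphabet).
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Silhouette-based scan for the number of groups
#'
#' Mean silhouette width of the Ward tree cut at each candidate k,
#' using the same z-scored Euclidean geometry as [cluster_samples()].
#'
#' @param x transformed gene x sample matrix.
#' @param k_range candidate group counts (default 2:6).
#' @return data frame: k, mean_silhouette.
#' @export
scan_k <- function(x, k_range = 2:6) {
  z <- t(scale(t(x[row_vars(x) > 0, , drop = FALSE])))
  d <- as.matrix(stats::dist(t(z)))
  hc <- stats::hclust(stats::as.dist(d), method = "ward.D2")
  sil_for <- function(k) {
    lab <- stats::cutree(hc, k = k)
    s <- vapply(seq_along(lab), function(i) {
      own <- lab == lab[i]
      own[i] <- FALSE
      if (!any(own)) return(0)
      a <- mean(d[i, own])
      b <- min(vapply(setdiff(unique(lab), lab[i]),
                      function(g) mean(d[i, lab == g]), 0))
      (b - a) / max(a, b)
    }, 0)
    mean(s)
  }
  data.frame(k = k_range,
             mean_silhouette = vapply(k_range, sil_for, 0))
}
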