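#' Read a BED3/BED6 file of fragment or peak intervals
#'
#' @param path BED file (0-based half-open, tab-separated, no header).
#' @return data frame with chrom, start, end and, when present, name,
#'   score, strand.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "name",
                                       "score", "strand")[1:6],
                         fill = TRUE)
  x <- x[, colSums(!is.na(x) & x != "") > 0, drop = FALSE]
  bad <- which(x$start >= x$end)
  if (length(bad))
    stop("malformed interval (start >= end) at line ", bad[1L])
  x
}

#' Write intervals as BED
#' @param x data frame with at least chrom, start, end.
#' @param path output file.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  utils::write.table(x[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GTF annotation
#'
#' Keeps `gene` feature rows (falling back to the union range of each
#' gene_id's exons when the file has no gene rows) and converts the GTF
#' 1-based closed coordinates to the 0-based half-open convention used
#' throughout the package.
#'
#' @param path GTF file.
#' @return data frame: gene_id, chrom, start, end, strand.
#' @export
read_gtf_genes <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                         comment.char = "#", stringsAsFactors = FALSE)
  names(x) <- c("chrom", "source", "feature", "start", "end",
                "score", "strand", "frame", "attributes")
  gid <- sub('.*gene_id[ =]+"?([^";]+)"?.*', "\\1", x$attributes)
  if (any(x$feature == "gene")) {
    keep <- x$feature == "gene"
    out <- data.frame(gene_id = gid[keep], chrom = x$chrom[keep],
                      start = x$start[keep] - 1L, end = x$end[keep],
                      strand = x$strand[keep], stringsAsFactors = FALSE)
  } else {
    sp <- split(seq_len(nrow(x)), gid)
    out <- do.call(rbind, lapply(names(sp), function(g) {
      i <- sp[[g]]
      data.frame(gene_id = g, chrom = x$chrom[i[1L]],
                 start = min(x$start[i]) - 1L, end = max(x$end[i]),
                 strand = x$strand[i[1L]], stringsAsFactors = FALSE)
    }))
  }
  if (anyDuplicated(out$gene_id))
    stop("duplicate gene_id in annotation: ",
         out$gene_id[duplicated(out$gene_id)][1L])
  rownames(out) <- NULL
  out
}

#' Read a chrom.sizes table
#' @param path two-column TSV: chromosome name, length in bp.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  stats::setNames(as.integer(x[[2L]]), x[[1L]])
}

#' Read / write a gene x sample count matrix as TSV
#'
#' The first column, `gene_id`, keys the rows.
#' @param path TSV file.
#' @return integer matrix with gene rownames.
#' @export
read_counts_tsv <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(x[, -1L, drop = FALSE])
  rownames(m) <- x[[1L]]
  validate_counts(m)
  m
}

#' @rdname read_counts_tsv
#' @param counts matrix to write.
#' @export
write_counts_tsv <- function(counts, path) {
  utils::write.table(
    data.frame(gene_id = rownames(counts), counts, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_counts <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0)) stop("negative counts")
  invisible(counts)
}
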