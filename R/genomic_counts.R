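# Interval arithmetic is delegated to IRanges/GenomicRanges; all
# user-facing coordinates stay BED-style 0-based half-open and are
# shifted to the 1-based closed convention only at the GRanges border.

as_granges0 <- function(x, what = "interval") {
  bad <- which(x$start >= x$end)
  if (length(bad))
    stop("malformed ", what, " (start >= end) at line ", bad[1L])
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end))
}

#' Count fragments per gene body
#'
#' A fragment increments a gene when it overlaps the gene body by at
#' least 1 bp; a fragment overlapping several genes increments all of
#' them. Strand is ignored (5hmC capture is not strand-resolved).
#'
#' @param fragments data frame of fragment intervals (chrom, start,
#'   end; 0-based half-open).
#' @param genes data frame of gene models (gene_id, chrom, start, end).
#' @return named integer vector of per-gene counts.
#' @export
count_gene_bodies <- function(fragments, genes) {
  gr_genes <- as_granges0(genes, "gene")
  if (nrow(fragments) == 0L)
    return(stats::setNames(integer(nrow(genes)), genes$gene_id))
  gr_frag <- as_granges0(fragments, "fragment")
  n <- GenomicRanges::countOverlaps(gr_genes, gr_frag,
                                    minoverlap = 1L, ignore.strand = TRUE)
  stats::setNames(as.integer(n), genes$gene_id)
}

#' Count fragments in fixed-width genomic bins
#'
#' Tiles each chromosome `[0, size)` into half-open bins of
#' `bin_width` bp (the last bin truncated at the chromosome end) and
#' assigns every fragment to each bin it overlaps. Fragments running
#' past a chromosome end are clipped with a warning.
#'
#' @param fragments fragment intervals as in [count_gene_bodies()].
#' @param chrom_sizes named vector of chromosome lengths.
#' @param bin_width bin width in bp (default 1000).
#' @return data frame: chrom, start, end (0-based half-open), count.
#' @export
count_bins <- function(fragments, chrom_sizes, bin_width = 1000L) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  bins <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    sz <- chrom_sizes[[ch]]
    starts <- seq(0L, sz - 1L, by = bin_width)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_width, sz),
               stringsAsFactors = FALSE)
  }))
  if (nrow(fragments)) {
    unknown <- setdiff(unique(fragments$chrom), names(chrom_sizes))
    if (length(unknown))
      stop("fragments on chromosome(s) missing from chrom_sizes: ",
           paste(unknown, collapse = ", "))
    lim <- chrom_sizes[fragments$chrom]
    if (any(fragments$end > lim)) {
      warning(sum(fragments$end > lim),
              " fragment(s) beyond chromosome end; clipped")
      fragments$end <- pmin(fragments$end, lim)
      fragments <- fragments[fragments$start < fragments$end, , drop = FALSE]
    }
  }
  cnt <- if (nrow(fragments) == 0L) integer(nrow(bins)) else
    GenomicRanges::countOverlaps(as_granges0(bins, "bin"),
                                 as_granges0(fragments, "fragment"),
                                 ignore.strand = TRUE)
  bins$count <- as.integer(cnt)
  bins
}

#' Collapse duplicate fragments
#'
#' Fragments identical in (chrom, start, end, strand) are collapsed to
#' one copy, mirroring duplicate-read removal in 5hmC libraries.
#'
#' @param fragments fragment data frame; a missing strand column is
#'   treated as unstranded.
#' @return list with `fragments` (deduplicated, original order of first
#'   occurrence) and `duplicate_rate` = 1 - unique/total (0 for empty
#'   input).
#' @export
deduplicate <- function(fragments) {
  if (nrow(fragments) == 0L)
    return(list(fragments = fragments, duplicate_rate = 0))
  strand <- if ("strand" %in% names(fragments)) fragments$strand else "."
  key <- paste(fragments$chrom, fragments$start, fragments$end, strand)
  keep <- !duplicated(key)
  list(fragments = fragments[keep, , drop = FALSE],
       duplicate_rate = 1 - sum(keep) / nrow(fragments))
}

REGION_CATEGORIES <- c("CDS", "5'UTR", "3'UTR", "intron", "intergenic")

#' Classify enriched regions by genomic feature
#'
#' Assigns each peak a single category by the feature containing its
#' midpoint, with fixed priority CDS > 5'UTR > 3'UTR > intron >
#' intergenic, and reports the category proportions (the genome
#' distribution of 5hmC-enriched regions).
#'
#' @param peaks data frame of peak intervals (chrom, start, end).
#' @param annotation data frame of feature intervals with a `category`
#'   column using labels "CDS", "5'UTR", "3'UTR", "intron".
#' @return named numeric vector of proportions over
#'   (CDS, 5'UTR, 3'UTR, intron, intergenic), summing to 1.
#' @export
classify_regions <- function(peaks, annotation) {
  if (nrow(peaks) == 0L)
    stop("empty peak list: proportions undefined")
  need <- setdiff(c("CDS", "5'UTR", "3'UTR", "intron"),
                  unique(annotation$category))
  if (length(need))
    stop("annotation missing categories: ", paste(need, collapse = ", "))
  mid <- peaks$start + (peaks$end - peaks$start) %/% 2L
  pts <- data.frame(chrom = peaks$chrom, start = mid, end = mid + 1L)
  gr_pts <- as_granges0(pts, "peak")
  assigned <- rep("intergenic", nrow(peaks))
  for (cat in rev(setdiff(REGION_CATEGORIES, "intergenic"))) {
    feat <- annotation[annotation$category == cat, , drop = FALSE]
    if (nrow(feat) == 0L) next
    hit <- GenomicRanges::countOverlaps(
      gr_pts, as_granges0(feat, "feature"), ignore.strand = TRUE) > 0L
    assigned[hit] <- cat
  }
  tab <- table(factor(assigned, levels = REGION_CATEGORIES))
  prop <- as.numeric(tab) / nrow(peaks)
  stats::setNames(prop, REGION_CATEGORIES)
}
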