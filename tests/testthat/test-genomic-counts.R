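test_that("gene-body counting follows the >= 1 bp overlap rule", {
  gene <- data.frame(gene_id = "g1", chrom = "chr1",
                     start = 100L, end = 200L)
  fr <- frag("chr1", c(150L, 90L, 250L), c(160L, 105L, 260L))
  expect_equal(unname(count_gene_bodies(fr, gene)), 2L)

  # empty fragment list gives all-zero counts
  expect_equal(count_gene_bodies(fr[0, ], toy_genes()),
               c(gA = 0L, gB = 0L, gC = 0L))

  # a fragment spanning two adjacent genes increments both
  two <- data.frame(gene_id = c("L", "R"), chrom = "chr1",
                    start = c(0L, 100L), end = c(100L, 200L))
  spanning <- frag("chr1", 90L, 110L)
  expect_equal(count_gene_bodies(spanning, two), c(L = 1L, R = 1L))

  # malformed intervals are rejected with their line number
  bad <- frag("chr1", c(10L, 50L), c(20L, 40L))
  expect_error(count_gene_bodies(bad, gene), "line 2")
})

test_that("gene-body counting is invariant to fragment order", {
  genes <- toy_genes()
  fr <- simulate_fragments(genes, c(20L, 15L, 10L), seed = 3)
  perm <- fr[sample(nrow(fr)), ]
  expect_equal(count_gene_bodies(fr, genes),
               count_gene_bodies(perm, genes))
})

test_that("fragment simulation and gene counting round-trip exactly", {
  genes <- toy_genes()
  wanted <- c(gA = 17L, gB = 0L, gC = 31L)
  fr <- simulate_fragments(genes, wanted, seed = 11)
  expect_equal(count_gene_bodies(fr, genes), wanted)
})

test_that("bin counting tiles half-open bins and clips overhangs", {
  sizes <- c(chr1 = 3000L)
  # fragment straddling a bin boundary increments both bins
  b <- count_bins(frag("chr1", 995L, 1005L), sizes)
  expect_equal(b$count, c(1L, 1L, 0L))
  expect_equal(b$start, c(0L, 1000L, 2000L))
  # fully inside one bin: exactly one bin incremented
  b2 <- count_bins(frag("chr1", 1100L, 1200L), sizes)
  expect_equal(sum(b2$count), 1L)
  # mass identity: total >= fragments, equality iff no boundary crossed
  fr <- frag("chr1", c(10L, 995L, 2100L), c(20L, 1005L, 2200L))
  b3 <- count_bins(fr, sizes)
  expect_equal(sum(b3$count), nrow(fr) + 1L)
  expect_warning(b4 <- count_bins(frag("chr1", 2900L, 3100L), sizes),
                 "clipped")
  expect_equal(sum(b4$count), 1L)
})

test_that("duplicate collapsing counts identical fragments once", {
  fr <- frag("chr1", c(10L, 10L, 50L, 80L), c(20L, 20L, 60L, 90L))
  dd <- deduplicate(fr)
  expect_equal(nrow(dd$fragments), 3L)
  expect_equal(dd$duplicate_rate, 0.25)

  all_same <- frag("chr1", rep(10L, 10L), rep(20L, 10L))
  dd2 <- deduplicate(all_same)
  expect_equal(nrow(dd2$fragments), 1L)
  expect_equal(dd2$duplicate_rate, 0.9)

  expect_equal(deduplicate(fr[!duplicated(fr), ])$duplicate_rate, 0)
  expect_equal(deduplicate(fr[0, ])$duplicate_rate, 0)
  # strand distinguishes otherwise identical fragments
  stranded <- frag("chr1", c(10L, 10L), c(20L, 20L), strand = c("+", "-"))
  expect_equal(nrow(deduplicate(stranded)$fragments), 2L)
})

test_that("region classification uses midpoint membership with priority", {
  anno <- data.frame(
    chrom = "chr1",
    start = c(0L, 100L, 300L, 500L, 100L),
    end = c(100L, 300L, 500L, 600L, 600L),
    category = c("5'UTR", "CDS", "intron", "3'UTR", "intron"),
    stringsAsFactors = FALSE)
  # midpoint in a CDS that also lies in another transcript's intron
  expect_equal(classify_regions(frag("chr1", 150L, 250L), anno)[["CDS"]], 1)
  # midpoint outside all features is intergenic
  expect_equal(
    classify_regions(frag("chr1", 700L, 800L), anno)[["intergenic"]], 1)
  # proportions: 2 intron, 1 CDS
  peaks <- frag("chr1", c(310L, 320L, 150L), c(490L, 480L, 250L))
  pr <- classify_regions(peaks, anno)
  expect_equal(pr[["intron"]], 2 / 3)
  expect_equal(pr[["CDS"]], 1 / 3)
  expect_equal(sum(pr), 1, tolerance = 1e-9)
  expect_error(classify_regions(peaks[0, ], anno), "empty peak")
  expect_error(classify_regions(peaks, anno[anno$category != "CDS", ]),
               "missing categories")
})

test_that("BED and GTF readers agree on coordinates", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tp1\t0\t+", bed)
  x <- read_bed(bed)
  expect_equal(x$start, 100L)
  gtf <- tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "src", "gene", "101", "200", ".", "+", ".",
                   'gene_id "gA";', sep = "\t"), gtf)
  g <- read_gtf_genes(gtf)
  # GTF 1-based closed -> 0-based half-open matches the BED interval
  expect_equal(g$start, x$start)
  expect_equal(g$end, x$end)
  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t300\t250"), bad)
  expect_error(read_bed(bad), "line 2")
})

test_that("count matrix TSV round-trips", {
  m <- matrix(1:6, 2, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  path <- tempfile(fileext = ".tsv")
  write_counts_tsv(m, path)
  expect_equal(read_counts_tsv(path), m)
})
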