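# Shared fixtures, all built in code at test time.

# a small toy annotation: three genes on two chromosomes
toy_genes <- function() {
  data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000L, 10000L, 500L),
    end = c(9000L, 20000L, 5000L),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE)
}

frag <- function(chrom, start, end, strand = "+") {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

# cohort config small enough for fast unit tests but with the full
# three-group / three-timepoint structure
small_config <- function(seed = 1L, ...) {
  simulation_config(
    seed = seed, n_genes = 400L,
    target_sets = list(androgen_response = 1:40,
                       immune_response = 41:100),
    signature_genes_per_group = 60L,
    ...)
}

# all structure switched off: pure NB noise around mu
null_config <- function(seed = 1L, n_genes = 200L, group_sizes = c(25L, 25L),
                        timepoints = "baseline", mu = 50, alpha = 0, ...) {
  simulation_config(
    seed = seed, n_genes = n_genes, group_sizes = group_sizes,
    timepoints = timepoints, baseline_mu = mu, dispersion = alpha,
    effect_log2fc = data.frame(set = character(), group = character(),
                               timepoint = character(), log2fc = numeric()),
    target_sets = list(androgen_response = seq_len(min(97L, n_genes))),
    patient_effect_sd = 0, signature_genes_per_group = 0L,
    hazard_beta = 0, ...)
}

# brute-force activity score: literal mean of log2 ratios
brute_score <- function(patient, control, genes, pseudocount = 1) {
  vals <- vapply(genes, function(g)
    log2(patient[[g]] + pseudocount) - log2(control[[g]] + pseudocount), 0)
  100 * mean(vals)
}
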