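# cfhmc — cell-free DNA 5hmC profiling pipeline

`cfhmc` is an R package for analysing 5-hydroxymethylcytosine (5hmC)
enrichment sequencing of plasma cell-free DNA in a longitudinal cancer
cohort — the kind of liquid-biopsy study that profiles patients at the
start of androgen deprivation therapy (ADT), after 3 months of
treatment, and at progression or end of follow-up, against a panel of
healthy plasma controls. 5hmC is enriched over active gene bodies, so
per-gene counts of 5hmC-captured cfDNA fragments act as a circulating
read-out of gene activation.

The package implements the full analysis path:

* **Counting & QC** — gene-body and 1 kb-bin fragment counting
  (0-based half-open BED coordinates; GTF converted on read),
  duplicate-fragment collapsing, genomic classification of enriched
  regions (CDS / 5'UTR / 3'UTR / intron / intergenic by midpoint with
  fixed priority), and spike-in enrichment QC over C / 5mC / 5hmC
  control amplicons.
* **Normalization** — the median-of-ratios size-factor estimator, a
  median-count gene filter (default: median raw count ≥ 8), and a
  shifted-log transform for clustering/visualization.
* **Differential 5hmC methylation** — a negative-binomial Wald test
  with moment-based, mean-rank-smoothed dispersions, a Welch *t*
  alternative, Benjamini–Hochberg FDR, and DMG calling at FDR < 0.1.
* **Gene-set analysis** — exact hypergeometric over-representation of
  DMG lists (GMT input) and the package's core statistic, the
  **gene-set activity score**:

  ```
  ActivityScore = 100/n * sum_i [ log2(RC_i^patient) - log2(RC_i^control) ]
  ```

  the mean log2 ratio between a patient's normalized gene-body counts
  and a pooled healthy control, over the `n` genes of a set, scaled by
  100. Zero means healthy-like; positive means the set is
  hypermethylated (activated).
* **Subgrouping & survival** — Ward clustering + PCA of DMG profiles
  into epigenomic groups (EpiGroups, numbered by descending
  androgen-set score), Kaplan–Meier curves, the Mantel–Cox log-rank
  test, a Breslow/Newton–Raphson Cox model for the hazard ratio of
  high- vs low-score patients (median cutoff), ANCOVA adjustment for
  clinical covariates, and paired longitudinal score dynamics.
* **Synthetic cohorts** — a seeded generator
  (`simulation_config()` / `simulate_cohort()`) that produces
  negative-binomial counts for ~20k genes with three latent EpiGroups,
  an androgen-response-like program that is high at baseline,
  suppressed at month 3 and rebounding at progression, exponential
  progression times whose hazard rises with the true baseline score,
  24-month censoring, spike-in reads, fragments and sample sheets — so
  the entire pipeline is testable with no external data.

## Worked example

```r
library(cfhmc)

cfg <- pipeline_config(outdir = "demo_run", seed = 42)
res <- run_pipeline(cfg)

base_ids <- paste0(names(res$cohort$truth$groups), "_baseline")
a <- subset(res$scores, set == "androgen_response" &
                        sample_id %in% base_ids)
cmp <- compare_scores(
  a, setNames(paste0("EpiGroup", res$epigroups$labels[base_ids]),
              base_ids))
print(cmp$summary, digits = 3)
print(res$survival$cox)
```

The run log and the printed results:

```
simulate: 20000 genes x 172 samples, seed 42
qc: 172/172 libraries pass >= 100-fold spike-in enrichment
normalize: 19999/20000 genes kept (median >= 8)
diffmeth: 1722 DMGs (FDR < 0.1): 949 hyper, 773 hypo
enrich: top set 'EpiGroup1_up' (FDR 1.78e-307)
score: 165 samples x 8 sets
cluster: k = 3, sizes 6/18/31
survival: log-rank p = 0.05709, HR = 2.51 (p = 0.06611)
dynamics: 48 paired contrasts

                set     group  n mean   sd
1 androgen_response EpiGroup1  6 24.2 3.83
2 androgen_response EpiGroup2 18 -3.5 3.73
3 androgen_response EpiGroup3 31 -4.8 5.45
Cox PH: HR = 2.509 (log HR 0.9200 +/- 0.5006), Wald p = 0.06611
```

Reading this: of 55 simulated patients, the 1,722 genes differing
between progressed and non-progressed patients at baseline are
overwhelmingly drawn from the progressing subgroup's epigenomic
signature (`EpiGroup1_up`); unsupervised clustering recovers the three
latent groups; EpiGroup 1's androgen-response activity score sits
around +24 (a designed +0.25 log2 activation, ×100 scale) while the
other groups sit slightly below zero — the score formula compares a
single sample's log count with the log of a control mean, which puts
healthy-like samples a few points negative. Patients above the median
score progress faster (HR ≈ 2.5 here; the generator's design target
across the median split is a true HR of 3, and any single 55-patient
cohort estimates it noisily). The run directory contains one TSV per
stage plus a `manifest.json` with an MD5 checksum of every output, so
re-running with the same seed is verifiably identical.

Every stage is equally usable on real data: `read_bed()` /
`read_gtf_genes()` / `count_gene_bodies()` build the count matrix from
aligned fragments, `load_gmt()` brings in gene-set collections, and
`pipeline_config(counts = ..., sample_sheet = ..., sets = ...)` runs
the same stages on supplied inputs. A command-line wrapper lives at
`inst/scripts/cfhmc-run.R`.

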