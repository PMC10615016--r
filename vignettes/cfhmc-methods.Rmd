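---
title: "Models and methods behind cfhmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cfhmc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfhmc)
```

# Overview

`cfhmc` analyses plasma cell-free DNA (cfDNA) 5-hydroxymethylcytosine
(5hmC) enrichment sequencing in a longitudinal cancer cohort. 5hmC is an
oxidized DNA methylation mark enriched over active gene bodies, so the
per-gene abundance of 5hmC-captured cfDNA fragments acts as a liquid-biopsy
proxy of gene activation in the tissues shedding the DNA. The pipeline
covers the path from aligned fragment intervals to clinical read-outs:

1. gene-body / 1 kb-bin fragment counting, duplicate collapsing and
   spike-in enrichment QC;
2. gene filtering and median-of-ratios normalization;
3. negative-binomial (and Welch) differential 5hmC methylation with
   Benjamini–Hochberg correction;
4. hypergeometric over-representation of gene sets in the
   differentially methylated genes (DMGs);
5. per-sample **gene-set activity scores** against a pooled healthy
   control;
6. unsupervised epigenomic subgrouping (Ward clustering + PCA);
7. progression-free survival analysis (Kaplan–Meier, log-rank, Cox,
   median-score dichotomization, ANCOVA adjustment); and
8. longitudinal score dynamics across treatment timepoints.

Because the patient data the design is modeled on are not public, the
package ships a first-class cohort simulator; every statistical claim the
test suite makes is evaluated on synthetic cohorts whose construction is
described below.

# The activity score

For a patient sample $P$, a pooled healthy control $C$ and a gene set
$G$ with $n$ usable genes, the score is

$$ \mathrm{ActivityScore}(P, G) \;=\; \frac{100}{n} \sum_{i \in G}
   \left[ \log_2 (RC_i^P + c) - \log_2 (RC_i^C + c) \right] $$

where $RC_i^P$ is the patient's size-factor-normalized count of gene
$i$, $RC_i^C$ is the **arithmetic mean** of the normalized counts of
gene $i$ over the healthy controls, and $c$ is a pseudocount. The score
is near 0 when the set's 5hmC level matches healthy plasma; +100 means
a uniform doubling.

Choices worth knowing about:

* **Pseudocount** ($c = 1$ by default). The bare formula is undefined at
  zero counts. `pseudocount = 0` evaluates the exact formula (and
  errors on zeros); the test suite uses it to verify the
  implementation against literal arithmetic.
* **Normalized scale.** "Normalized read count" is interpreted as
  size-factor-normalized counts, not the log-stabilized matrix; a
  patient's score therefore does not depend on the pseudocount used by
  the clustering transform.
* **Missing genes** are dropped (with a warning and an `n_genes_used`
  record), not zero-filled — zero-filling would manufacture infinite
  log-ratios.
* **Asymmetry bias.** The formula compares a *single* sample's log
  count with the log of a control *mean*. By Jensen's inequality the
  patient side carries the larger concavity bias, so under identical
  distributions the expected score is slightly negative, about
  $-72\,(\mathrm{E}[1/\mu] + \alpha)(1 - 1/n_c)$ score units for NB
  counts with mean $\mu$ and dispersion $\alpha$ pooled over $n_c$
  controls (about $-3$ to $-4$ units at the simulator defaults). This
  is a property of the score itself, not an implementation artifact;
  healthy-like groups in real cohorts scored with this formula sit a
  few points below zero, and the simulator reproduces that behavior.
  Scoring is done after gene filtering by default (`filter_genes`
  keeps per-gene median raw count ≥ 8), which keeps the $1/\mu$ part
  of the bias small.

# Normalization

Size factors are classical median-of-ratios: the reference is the
per-gene geometric mean over genes positive in every sample, and a
sample's factor is the median ratio of its counts to the reference.
Factors are rescaled to geometric mean 1, which changes nothing
downstream (all uses are ratio- or contrast-based) and makes factors
comparable across matrices.

The variance-stabilizing step used before clustering and visualization
is the shifted log, $\log_2(x/s_j + 1)$. It is deliberately *not* the
parametric dispersion-trend VST of count-model packages: the
transform's only role here is to tame the mean-variance relationship
for Euclidean clustering and plotting, and the pipeline's scientific
outputs (scores, tests, survival) never pass through it. The
simplification is documented rather than hidden.

# Differential 5hmC methylation

The two-group test is a negative-binomial Wald test built for gene-body
counts:

* group means $m_1, m_2$ are computed on the normalized scale;
* the per-gene NB dispersion $\alpha$ ($\mathrm{Var} = \mu + \alpha
  \mu^2$) is estimated by method of moments from the within-group
  pooled variance, then **median-smoothed within 50 mean-rank bins**
  and floored at $10^{-8}$. Smoothing borrows strength across genes of
  similar abundance; it is a declared simplification of empirical-Bayes
  dispersion shrinkage, adequate at cohort-scale group sizes;
* $\log_2\mathrm{FC} = \log_2\!\big((m_2 + 0.5)/(m_1 + 0.5)\big)$, a
  pseudo-mean of 0.5 guarding zero group means;
* the delta method under the NB variance gives the SE, a Wald $z$, and
  a two-sided normal $p$; BH adjustment runs across genes.

DMGs are called at FDR < 0.1 (strict inequality), split into
hypermethylated ($\log_2\mathrm{FC} > 0$) and hypomethylated. A Welch
$t$ alternative on the stabilized matrix is provided with explicit
degenerate-variance conventions (both groups constant and equal → $p =
1$; constant but unequal → $p = 0$). Timepoint contrasts reuse the
two-group machinery; the longitudinal report (`dynamics_report`) uses a
paired $t$ by default, the natural choice for serial samples from the
same subjects, with an unpaired fallback.

Calibration is part of the test suite: under a null NB simulation
(20 vs 20 samples, $\alpha = 0.1$) the Wald test's empirical type-I
error at $p < 0.05$ must stay within [0.03, 0.07].

# Gene-set enrichment

Over-representation of a DMG list in a gene-set collection uses the
exact hypergeometric upper tail $P(X \ge k)$ with the **filtered gene
list as the universe** — the frame in which the DMGs were tested — and
BH correction across sets. Rank-based enrichment (running-sum
statistics, permutation p-values) is out of scope: the evidence being
modeled is over-representation of a discrete DMG list.

# Epigenomic subgrouping

Samples are clustered on the stabilized matrix restricted to the DMGs:
genes are z-scored across samples, distances are Euclidean, linkage is
Ward (`ward.D2`), and the tree is cut at $k = 3$ by default. Ward on
z-scored profiles favors compact, balanced groups, which matches the
clean three-way structure the pipeline is designed to detect; a
silhouette-based `scan_k` is available when $k$ must be chosen from
data. Group labels are renumbered by descending mean androgen-set
activity score, so **group 1 is always the high-activity group** and
downstream reports are stable across runs. PCA (column-centered SVD
with a deterministic sign convention: the largest-magnitude loading of
each component is positive) accompanies the tree as independent
evidence of the group structure.

# Survival analysis

All survival machinery is implemented directly and cross-checked
against independent references in the tests:

* **Kaplan–Meier** product-limit curves with Greenwood variance;
  censoring at a tied time counts after the tie's events.
* **Log-rank** (Mantel–Cox) for two strata: $\chi^2 = (\sum O - E)^2 /
  \sum V$ on 1 df.
* **Cox proportional hazards** for a single covariate, maximizing the
  Breslow partial likelihood by Newton–Raphson (tolerance $10^{-8}$,
  ≤ 50 iterations), Wald SE from the observed information. Breslow tie
  handling is the simplest adequate choice for continuous synthetic
  times. Monotone likelihoods (complete separation) are flagged and
  the estimate capped at $|\log \mathrm{HR}| \le 10$.
* **Median dichotomization** of activity scores: strictly above the
  median is "high"; scores equal to the median go to "low" — a
  deterministic tie rule that is conservative for the high-risk group.
  The hazard ratio is reported for high vs low, so HR > 1 means worse
  outcome.
* **ANCOVA**: OLS of the score on the group indicator plus clinical
  covariates (baseline PSA, ctDNA fraction), with the group effect
  tested by partial F against the covariates-only model. If the group
  indicator is entirely absorbed by the covariates the adjusted effect
  is reported as F = 0 rather than an error; collinearity among the
  covariates themselves is an error naming the offending columns.

# The synthetic cohort generator

`simulate_cohort()` draws NB gene-body counts,
$\mathrm{NB}(\mu_g f_s 2^{\delta_{gs}}, \alpha)$, for patients at three
timepoints and for healthy controls (who appear once, at a baseline
pseudo-timepoint). The defaults are the package's model of a realistic
ADT cohort, chosen once and documented here:

* **Cohort shape**: 55 patients in three latent EpiGroups (6/31/18)
  plus 7 healthy controls; ~20,000 genes; 24-month administrative
  censoring.
* **Depth and noise**: per-gene means $\mu_g \sim
  \mathrm{LogNormal}(\log 300, 1)$ (tens-of-millions-of-reads
  libraries spread over ~20k genes give gene-body means of a few
  hundred), library-size factors $\mathrm{LogNormal}(0, 0.15)$,
  dispersion $\alpha = 0.05$ (cross-patient CV ≈ 22%, appropriate for
  counts aggregated over whole gene bodies; it reproduces within-group
  activity-score SDs of ≈ 4–5 units).
* **Group signatures**: each EpiGroup carries a private, stable
  signature — 3,000 genes outside the target sets with
  $N(0, 0.75)$ log2 shifts, constant across timepoints and absent from
  controls. Epigenomic subgroups in real cohorts differ over thousands
  of genes; without such signatures a three-way unsupervised split
  would be unidentifiable.
* **Target-set program**: the 97-gene androgen-response-like set is
  shifted $+0.25$ log2 in EpiGroup 1 at baseline, $0$ at month 3
  (therapy suppresses the pathway) and $+0.3$ at the endpoint
  (rebound at progression); an immune-like 200-gene set is shifted
  $-0.2$ at baseline and endpoint. On the ×100 score scale the
  baseline androgen effect is +25.
* **Patient-level variation**: every patient gets a persistent random
  activation of each target set, $N(0, 4)$ score units. This is what
  makes the *continuous* score prognostic rather than a pure
  group label, and it matches the within-group spread seen in real
  score distributions.
* **Survival**: event times are exponential with
  $\log h = \log h_0 + \beta \cdot \mathrm{score}_{\mathrm{true}}$,
  $h_0 = 0.015$/month (≈ 20 of 55 progress within 24 months). By
  default $\beta$ is calibrated per cohort so that the median-score
  split a downstream analyst forms — true score plus the count-model
  measurement noise, whose SD
  $\frac{100}{\ln 2}\sqrt{\overline{(1/\mu + \alpha)}/n}$ (≈ 3.4 units
  at the defaults) follows from the NB model — separates strata whose
  *true* hazards differ by exactly 3×. Calibrating on the analyst's
  split rather than the latent one keeps the hazard ratio that Cox
  estimates centered on the design target. `hazard_beta` can be fixed
  instead (0 gives a null cohort).
* **Spike-ins**: binomial capture of 0.2 million copies per amplicon
  class, 5hmC capture efficiency 0.5, background rate 0.004 — an
  expected ≈ 125-fold enrichment, comfortably above the 100-fold pass
  threshold.

The generator is seeded end to end: identical configuration and seed
give byte-identical outputs, which the pipeline manifest (MD5 per stage
output) makes checkable.

**What the simulator does not model** — and hence what passing tests do
not establish about real data: GC and mappability bias, fragment-level
end motifs, correlated gene-gene noise, ctDNA-fraction structure,
informative censoring, batch effects, and alignment artifacts. Results
on synthetic cohorts validate the statistical machinery, not the
biology of any particular dataset.

# Numerical conventions and degenerate inputs

* Coordinates are BED-style 0-based half-open everywhere; GTF input
  (1-based closed) is converted on read. Strand is ignored for
  counting (5hmC capture is not strand-resolved).
* Counting uses a ≥ 1 bp overlap rule; a fragment overlapping several
  genes increments all of them.
* Peaks are classified by midpoint membership with fixed priority
  CDS > 5'UTR > 3'UTR > intron > intergenic.
* Even-length medians are the mean of the two middle values
  (gene filter, score dichotomization).
* The spike-in fold enrichment is the copy-normalized 5hmC rate over
  the mean of the C and 5mC rates; the 100-fold pass threshold is
  inclusive, zero background with non-zero 5hmC signal passes with an
  infinite-fold flag, and an all-zero spike-in table fails with
  "no spike-in signal".
* BH adjustment is the step-up definition evaluated exactly; p-values
  outside [0, 1] are an error, never clamped.

# Problem sizes used by the test suite

Unit tests run on matrices of tens to hundreds of genes. The
property-based checks use: 1,000 random score fixtures; 200 random
p-vectors (length ≤ 1,000) for the BH oracle; exhaustive hypergeometric
enumeration for all universes up to N = 12; 2,000 null genes (20 vs 20)
and 500 null survival replicates for calibration; and 50 replicate
default cohorts (20,000 genes, 55 patients, 3 timepoints) for the
end-to-end recovery checks — sizes chosen so the full suite completes
in minutes on a single CPU while keeping every check's Monte-Carlo
error far below its decision margin.

# Known limitations

* The NB dispersion smoothing is cruder than empirical-Bayes
  shrinkage; at very small group sizes (< 5 per group) the Wald test
  can drift from nominal calibration.
* Paired timepoint DMG contrasts reuse the unpaired two-group
  machinery (the score dynamics report, by contrast, is properly
  paired).
* The Cox implementation covers the single-covariate case the pipeline
  needs; multivariable hazard modeling is out of scope.
* The exact VST curve of count-model packages is intentionally not
  replicated (see Normalization).
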