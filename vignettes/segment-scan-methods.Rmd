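---
title: "Segment-wise enrichment scans: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segment-wise enrichment scans: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segwise)
```

## The model

`segwise` tests a spatial hypothesis about the genetic architecture of a
complex disorder: that risk variants of individually negligible effect
are not scattered uniformly but *collocated* in chromosomal segments at
a scale far wider than single genes (megabases), for instance because
co-regulated genes cluster in expression domains or chromatin
territories.  Under that hypothesis a large window can carry a
detectable *excess of nominally significant SNPs* even when no single
SNP survives genome-wide correction.

The statistic chain is deliberately simple:

* **Per SNP**: the Armitage trend chi-square, computed as $N r^2$ with
  $r$ the Pearson correlation between dosage $x \in \{0,1,2\}$ and the
  phenotype over the $N$ individuals non-missing at that SNP.  On a 0/1
  phenotype this is algebraically identical to the classical
  Cochran–Armitage trend statistic with scores $(0,1,2)$ (the test
  suite verifies this against a contingency-table oracle), and it
  extends unchanged to the continuous residual phenotypes produced by
  the stratification adjustment.  It is invariant under allele
  relabeling ($x \mapsto 2-x$), so no minor-allele re-orientation is
  performed.
* **Per segment**: the count of member SNPs with $p <$ `nominal_alpha`
  (strict inequality; default 0.05).  Counting is the aggregation that
  buys power: a segment with hundreds of SNPs each at 10–20% power can
  show a large, stable excess.
* **Null**: global permutation of case/control labels.  SNPs in
  linkage disequilibrium (LD) make the count over-dispersed relative to
  a binomial, so an analytic independence null would be anti-
  conservative; permuting the labels once per replicate and recomputing
  *all* SNP tests preserves the full LD structure.  The segment-level
  *metasignificance* is $(1 + \#\{\text{null count} \ge
  \text{observed}\})/(B+1)$, one-sided (only an excess is signal), with
  floor $1/(B+1)$ — with the conventional $B = 1000$, the smallest
  reportable value is $\approx 0.001$.
* **Across cohorts**: cohorts genotyped on different arrays are never
  pooled; only their per-segment p-values meet.  Two channels are
  reported side by side: the *compound-significance* rule (replicable
  iff every cohort's metasignificance is below
  $t = (\alpha/N)^{1/k}$, so the joint false-positive rate is
  $t^k = \alpha/N$) and Fisher's combined probability
  $-2\sum_i \ln p_i \sim \chi^2_{2k}$, which is less sensitive to
  near-threshold permutation noise.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| segment widths | 2–32 Mbp | scan scales; 50% overlap on every lattice |
| `nominal_alpha` | 0.05 | per-SNP count threshold (0.01 / 0.1 in sensitivity runs) |
| `n_permutations` | 1000 | permutation floor $1/(B+1) \approx 0.001$ |
| worst-case N | 2729 | 2 Mbp segment count used for the Bonferroni family level |
| `per_sample_threshold` | 0.0264 | $((0.05/2729))^{1/3} = 0.026356$, i.e. 0.0264 at 3 s.f. |
| `eigenstrat_components` | 0 (10 when adjusting) | PCs removed from the phenotype |
| set test | r² ≤ 0.5, p < 0.05, ≤ 5 SNPs | conventional set-based defaults |

Two conventions are fixed once, package-wide: SNP positions are 1-based
(as in `.bim` files) and all intervals — lattice segments, targeted
regions, gene intervals after input conversion — are half-open
`[start, end)` in base pairs.  Segment lattices are anchored at
position 0 of each chromosome and extend through the last window whose
start does not pass the outermost SNP; the published replicable regions
at every width all lie on these lattices, which the acceptance suite
checks.

No correction is applied *across* widths: overlapping widths test
nearly the same hypothesis on the same data, so a cross-width
correction would be badly conservative.  Widths are reported side by
side and held to the same family level (the worst-case 2 Mbp count).

## Permutation design

One global label shuffle per replicate is shared by **all segments and
all widths** of a scan (`cmd_scan` passes the same seed to every
width).  This is both statistically necessary — per-segment shuffles
would destroy the inter-segment correlation that makes 50%-overlapping
windows comparable — and what makes 1000 replicates affordable: a
replicate costs two matrix products (four with missing data), so a
full-genome scan is a handful of BLAS calls.  Permutation indices are
drawn up-front from the mandatory integer seed, so results are
bit-identical across runs and independent of internal chunking; a
targeted-region test with the same seed reproduces the corresponding
lattice entry exactly.  R's default generator is used rather than a
counter-based per-replicate stream: the reproducibility contract is
carried by the single seed, and replicates are computed in-process.

All randomized entry points (`permutation_scan`, `set_based_test`,
`simulate_cohort`, the CLI subcommands) *refuse to run without a seed*.

## Stratification adjustment

Following the phenotype-residualization approach, case/control status
is regressed (logistic, IRLS tolerance $10^{-8}$, 100 iterations,
non-convergence is an error) on the top 10 principal components of the
EIGENSTRAT-standardized genotype matrix (columns centered and scaled by
$\sqrt{\hat p(1-\hat p)}$, missing set to 0 after centering), and the
*response residuals* replace the phenotype everywhere downstream.

A property worth knowing: residualizing the **phenotype only** removes
the anti-conservative inflation caused by confounded structure, but
under strong divergence it overshoots — the genotypes keep their
between-population variance while the residual keeps none, so observed
statistics are diluted relative to the permutation null and the
adjusted scan becomes *conservative* (this is visible in the test
suite, where an extreme two-population world drops the inflation factor
from ~4–15 to below 1).  In the unstructured limit the adjusted scan is
calibrated.  The acceptance suite therefore verifies (a) gross
anti-conservatism of the raw scan under confounding, (b) its removal by
adjustment, and (c) exact calibration of the adjusted scan without
structure — not exact calibration under extreme structure, which the
method does not provide.

## The synthetic world

The generator (`sim_config`/`simulate_cohort`) states the world the
method assumes, and its defaults are fixed:

* **Cohort sizes** default to 728 cases / 653 controls — the size of a
  typical single-country schizophrenia cohort; the multi-cohort tests
  use 728/653, 1172/1378 and 485/1363.
* **Marker density** defaults to one SNP per 5 kbp, the density of a
  ~550k genome-wide array on a ~2.8 Gbp genome.
* **LD** comes from per-block haplotype pools: 20 SNPs per block
  (100 kbp) drawn from 8 pool haplotypes with per-SNP frequencies
  uniform in [0.05, 0.5].  This gives strong within-block r² and
  essentially none between blocks — a deliberately blocky caricature
  chosen over coalescent simulation for controllability and desk-scale
  runtime.  Small pools make some SNPs monomorphic in the realized
  pool; those carry p = 1 by convention and are flagged.
* **Disease** follows a logistic liability with baseline prevalence 1%
  (schizophrenia-like): log-odds = intercept + $\ln(\mathrm{OR})$ per
  risk allele at each causal SNP (+ a subpopulation offset), intercept
  solved numerically so the population prevalence is met, then cases
  and controls rejection-sampled to exact counts.  Causal SNPs are a
  `planted_fraction` (default 0.3) of the SNPs in the planted interval
  at `planted_or` (default 1.08, the middle of the motivating 1.05–1.1
  band).
* **Stratification** is Balding–Nichols frequency divergence between
  two equal subpopulations plus an optional disease-probability offset,
  so confounded and unconfounded structure can both be generated.

What the generator does **not** emulate: realistic recombination-map LD
decay, allele-frequency spectra, array ascertainment, genotyping error
and missingness patterns, cryptic relatedness.  A green power or
calibration test therefore establishes that the *statistics* behave as
designed on data with block LD and weak clustered effects — not that
any particular real-data result would reproduce.  Reproducing the
published per-cohort permutation p-values and observed/expected counts
is out of reach by construction: the underlying genotypes are not
distributed.

One measurable premise of the approach is built into the test suite:
with per-SNP odds ratios in the 1.05–1.1 band and published cohort
sizes, essentially no single SNP reaches genome-wide significance
(5e-8) while the planted segment's metasignificance is strong — the
power gap the segment scan exists to close.

## Numerical and edge-case choices

* Monomorphic SNPs (zero dosage variance among tested individuals):
  statistic 0, p = 1, flagged — they can never contribute a nominal
  count.
* Missing dosages: pairwise deletion per SNP (`n_used` recorded); no
  imputation.  Missing phenotypes (`-9` in `.fam`) are dropped at load
  time with a warning.
* Empty segments are kept but flagged untestable and carry NA
  metasignificance; they are excluded from calibration summaries.
* The per-cohort threshold defaults to the *published* 0.0264 rather
  than the recomputed 0.026356...; the two agree at 3 significant
  figures and the parameter is explicit everywhere.
* Set-test score with zero selected SNPs is 0, which with the `>=`
  replicate comparison yields an empirical p of exactly 1 — matching
  the convention that a gene with no nominally significant member is
  simply null.
* The set-test statistic is the mean trend chi-square of the selected
  SNPs (the mean-of-statistics reading of the conventional set test;
  the alternative mean of $-\log p$ is monotone-equivalent per SNP but
  not per set, and the chi-square mean is the one adopted and
  documented here).
* Ties in the greedy selection (equal p) are broken by lower genomic
  position, making selection deterministic.

## Known limitations

* The PLINK 1 reader supports SNP-major `.bed` only (the format written
  since PLINK 1.0); individual-major files are rejected, not converted.
* Only autosomes (1–22) are analyzed; non-autosomal rows are dropped
  with a message.
* The worst-case segment count depends on the chromosome-extent
  convention (array coverage vs assembly length); on an hg18-like
  genome the 2 Mbp lattice lands in the 2.7–2.9k range, and the
  family-level arithmetic treats the published 2729 as the reference
  count.
* Permutation p-values are bounded below by $1/(B+1)$; Fisher
  combinations of floor values therefore understate the true joint
  evidence.
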