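---
title: "Methods: ROH calling, Froh burden regression, and the site-flip null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROH calling, Froh burden regression, and the site-flip null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohburden)
```

## The problem

Runs of homozygosity (ROH) — long stretches of consecutive homozygous
genotype calls — are the SNP-array signature of autozygosity: both
chromosome copies inherited identical-by-descent from a common ancestor.
The genomic inbreeding coefficient *Froh* is the fraction of the autosomal
genome covered by ROHs above a length threshold. If disease-predisposing
alleles are, on average, partially recessive (directional dominance),
individuals with higher *Froh* should carry higher disease risk, and a
case-control cohort should show a positive *Froh* burden association.

This package implements that analysis end to end for multi-site
case-control cohorts: quality control, LD pruning, ROH calling, *Froh* and
its short/long decomposition, covariate-adjusted logistic burden
regression with dataset fixed effects, and — the part that motivates the
synthetic-cohort machinery — a whole-site label-flip permutation null that
quantifies how badly site-level ascertainment differences inflate type-I
error in exactly this kind of analysis.

## ROH calling

`call_roh()` scans each sample and chromosome for maximal runs of
non-heterozygous calls and applies three rules, all tunable through
`calling_params()`:

| parameter | default | meaning |
|---|---|---|
| `min_snps_initial` | 40 | minimum consecutive homozygous SNPs per initial run |
| `max_het` | 0 (fixed) | no heterozygote calls allowed inside a run |
| `min_density_bp` | 200,000 | a segment must exceed 1 SNP per 200 kb |
| `gap_split_bp` | 500,000 | runs are split at inter-SNP gaps larger than 500 kb |

Numerical conventions worth stating precisely:

* Coordinates are 1-based inclusive; segment length is
  `end_bp − start_bp + 1`, and segment ends are the first/last run SNPs
  (no extension into flanking gaps).
* Density is evaluated per final segment (after gap-splitting) and must be
  *strictly* greater than 1/200 kb. A re-filter (`filter_roh()`) does not
  re-check density: the threshold sweep post-processes one fixed initial
  call, so a 110-SNP filtered set is exactly a subset of the 40-SNP call.
* Missing genotype calls terminate a run by default (the conservative
  reading of "no heterozygote calls allowed"); `missing_breaks = FALSE`
  makes them transparent — skipped, but not counted as run SNPs.
* A windowed heterozygote-tolerant scan is deliberately absent: with zero
  heterozygotes allowed, the common command-line caller's windowed
  algorithm reduces to the pure run scan implemented here.
* `filter_roh()` refuses thresholds below the calling floor (40 SNPs)
  rather than silently passing the unfiltered set through.

`call_roh()` is verified segment-for-segment against an independent naive
linear scan on 1,000 random genotype strings with random gap structures.

## Froh and the short/long decomposition

`compute_froh()` divides each sample's total ROH length by the
SNP-mappable autosomal distance, 2.77×10⁹ bases by default (pass the true
genome total for scaled synthetic genomes). `split_froh()` partitions at a
cutoff (8 Mb default, the variance-equalizing choice reproduced by
`variance_equalizing_cutoff()`): short ROHs index autozygosity from
distant common ancestors, long ROHs from recent ones. Two floating-point
decisions: segments exactly at the cutoff count as long (the strict
`<` / `>` definitions leave the boundary unassigned), and `froh` is
defined as `froh_short + froh_long` so the partition is exact in IEEE
arithmetic (this agrees with `total_bp / mappable_bp` to one ulp).
Per-dataset descriptives report SD = 0 for n = 1 and average segment
lengths over segments (not over per-sample means; the alternative is a
documented choice the tables could support).

## Quality control

`qc_thresholds()` carries the standard defaults: sample missingness
> 0.02, heterozygosity > 6 SD above the cohort mean (one-sided high),
relatedness π̂ > 0.2 (the pair member with higher missingness is dropped),
SNP Hardy-Weinberg exact p < 10⁻⁶ (all samples pooled; the
cases-excluded variant is a configuration away), SNP missingness > 0.02,
case-control missingness difference > 0.02, and VIF-based LD pruning at
VIF > 10 in 50-SNP windows (step 5 — the window size is standard, the
step is an implementation choice). Filters run samples-then-SNPs;
re-running QC on QC'd output removes nothing.

The Hardy-Weinberg test is the exact conditional test: given the observed
allele counts, all heterozygote counts of the same parity are enumerated
and those no more probable than the observed count are summed. It agrees
with full enumeration for every genotype configuration with n ≤ 50 and
with the χ² approximation at large, balanced counts.

π̂ is estimated as the off-diagonal of the genomic relationship matrix
(standardized-genotype covariance): ≈ 1 for duplicates, ≈ 0.5 for
first-degree pairs, centered a touch below 0 for unrelated samples
(the −1/(n−1) centering bias). This approximates the IBS-based
method-of-moments estimator of the usual tooling, which is all the 0.2
threshold needs; it is not a drop-in reimplementation of that estimator.

Ancestry outlier removal against external reference panels is out of
scope; `ancestry_outliers()` offers the panel-free reduction — distance
from the median centroid of the first two GRM PCs exceeding k = 6 times
the median distance. Median centroid and scale are used instead of
mean/SD because a strong outlier otherwise masks itself; note the PC
geometry bounds the ratio near √n, so the rule needs n ≳ 40 to fire.

## The burden model

Case-control status is regressed on *Froh* (proportion scale) by
maximum-likelihood logistic regression (`fit_logistic()`, IRLS with
step-halving; convergence when the largest score component is below
10⁻⁸, 25 iterations maximum). The adjustment set
(`build_covariates()`) is the field-standard one: 20 principal components
of the GRM built from the LD-pruned SNPs, per-sample missing rate, excess
heterozygosity (centered within dataset, since heterozygosity artifacts
are chip/site-specific), and dataset indicator columns as fixed effects.
Mixed-effects (random dataset) models are deliberately not offered —
fixed effects are the convergence-robust choice for this design.

The slope scale matters: with *Froh* in 0–1, a slope β corresponds to a
`100·(exp(β/100) − 1)` percent change in odds per additional 1% of the
genome autozygous (`or_per_percent()`); β = 16.1 gives +17.5%, the "about
17%" headline scale of the original report this pipeline reproduces in
simulation. Wald inference throughout: z = β/se, two-sided normal p,
95% CI = β ± 1.96·se.

Degenerate designs are flagged rather than mis-reported: aliased columns
are dropped via pivoted QR (constant *Froh* yields a flagged result with
no estimate), and fits pinned to the 0/1 boundary are flagged as
separation with `se = Inf`, `p = 1`. `fit_logistic()` matches `glm()` to
six decimals on well-posed problems; the agreement is part of the test
suite, while the in-package IRLS keeps convergence and failure semantics
explicit and dependency-free.

`sweep_association()` re-filters, recomputes *Froh*, and refits across the
40–200 SNP (step 10) and 1–20 Mb (step 1) threshold grids; per-point
failures are flagged rows, never sweep aborts. `interaction_test()` adds
a stratum flag and its product with *Froh*; `per_dataset_fits()` fits each
site separately (pooled PCs by default — dataset-specific PCs are a
supported alternative, with no claim that either is "the" published model)
plus the pooled fixed-effects fit.

## The synthetic cohort: what it emulates, what it does not

`cohort_spec()` describes a stated world chosen to mirror the structure
of the consortium replication data:

* 17 sites from ~200 to ~5,500 individuals (`default_site_sizes()`),
  roughly balanced case/control;
* 22 autosomes totaling 2.77×10⁹ bp, ~300K SNPs uniformly placed
  (tests use 2×10⁸ bp / 4 chromosomes at the same ~9 kb SNP spacing);
* MAF uniform on [0.15, 0.5] — the post-QC common-variant regime;
* per-individual autozygous fraction F from a 50:50 mixture of 0 and an
  exponential with mean 0.006, giving mean *Froh* ≈ 0.3% and SD ≈ 0.5%,
  matching the range of the per-site descriptive tables (0.1–1% on the
  ×100 scale);
* planted IBD segments with exponential lengths (mean 3 Mb, minimum
  0.5 Mb), drawn until the individual's F target is met, the last segment
  truncated to hit the target;
* a logistic liability `logit P(case) = α_site + β_true · F` on the
  *true* planted F — so attenuation by calling error is measurable — with
  retrospective ascertainment of the requested case/control counts
  (which preserves the slope);
* optional site-level ascertainment confounding: a per-site shift δ_s
  (drawn N(0, τ²) or supplied) added to the F of every case (δ_s > 0) or
  every control (δ_s < 0) *after* ascertainment, mimicking recruitment of
  one group from a more- or less-inbred source population rather than
  post-hoc label editing.

Genotypes are Hardy-Weinberg draws at each SNP's frequency, independent
across SNPs; inside planted segments every call is homozygous, class
drawn by allele frequency. **No LD is simulated** (the pipeline prunes LD
before calling anyway), no recombination maps, no coalescent haplotype
structure, no X chromosome. A green test therefore establishes that the
calling/statistics machinery is correct under the stated world — not that
the generator reproduces the LD-driven false-positive ROH structure of
real arrays.

Two layers are exposed deliberately. `simulate_cohort()` is the full
genotype-level generator; `simulate_froh_cohort()` is its genotype-free
statistical skeleton (true F, liability, ascertainment, confounding).
The large Monte-Carlo experiments — slope recovery at n = 10,000,
permutation calibration on ~31,500 samples, power at n = 40,000 — run on
the skeleton to stay within desk-scale CPU budgets; the genotype path is
validated separately (planted vs called *Froh* correlate > 0.95 for
F ≥ 0.005 at array density; a null cohort yields mean called
*Froh* < 5×10⁻⁴).

## The site-flip permutation null

`site_flip_permutation()` implements the degrees-of-freedom argument: per
permutation, every dataset independently keeps or inverts *all* its
phenotype labels with probability ½, and the pooled fixed-effects model
is refit (covariates are held fixed — flips do not alter genotypes; refit
failures count as non-significant, the conservative direction for
inflation claims). A whole-site flip negates, but never shrinks, that
site's *Froh*–phenotype association, so if sites carry random
ascertainment-induced *Froh* gaps the permutation distribution of the
pooled Wald statistic is far wider than N(0, 1): the effective degrees of
freedom are the number of sites, not the number of subjects.

In the package's stated world: with δ_s ≡ 0 the empirical type-I error at
α = 0.05 sits in the nominal band (0.03–0.08 at 500 permutations); with
δ_s ~ N(0, 0.001²) — shifts of a fifth of the *Froh* SD — it exceeds 0.10
and typically reaches 0.3–0.6. The published value of 0.18 for this
experiment was computed on the original 17 consortium datasets and is not
numerically reproducible without them; the tests here check the
mechanism and its direction, not that constant. `mode = "individual"`
(within-site label shuffling) restores calibration and completes the
argument.

`power_simulation()` closes the loop: at β_true = 16.1 with the default F
mixture, simulated power is ~100% at n = 40,000 and roughly halves at
n = 2,000, consistent with the >12,000 sample-size requirement cited for
realistic autozygosity effects.

## Known limitations

* No LD in the generator: false-positive ROH rates on unpruned real data
  are not represented; always prune before calling.
* The π̂ approximation can under-flag relatives on small SNP counts
  (SD ≈ 1/√m); the 0.2 threshold assumes a few thousand pruned SNPs.
* The .ped dialect has no REF/ALT: monomorphic variants register their
  observed allele as a1 (coded 0), so cross-format call identity holds up
  to the 2−g recoding; homozygosity, ROH and *Froh* are invariant.
* `variance_equalizing_cutoff()` is undefined when *Froh* is constant
  (error) and degenerates to the smallest grid value when no long
  segments exist; both behaviors are explicit.
* Imputed-genotype QC, dosage-r² filters and reference-panel ancestry
  filtering are out of scope.
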