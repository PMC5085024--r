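# rohburden

Runs-of-homozygosity (ROH) burden analysis for multi-site case-control
SNP cohorts, with a synthetic-cohort generator for studying the
calibration, power and confounding behavior of the burden test.

## The scientific problem

Autozygosity — both chromosome copies inherited identical-by-descent from
a common ancestor — exposes recessive deleterious alleles. On SNP arrays
it is measured through runs of homozygosity: long stretches of
consecutive homozygous calls. The genomic inbreeding coefficient

&nbsp;&nbsp;&nbsp;&nbsp;*F*<sub>ROH</sub> = (total bp in ROHs above a length threshold) / (SNP-mappable autosomal distance, 2.77×10⁹ bp)

is regressed on case-control status with logistic regression,

&nbsp;&nbsp;&nbsp;&nbsp;logit P(case) = β·*F*<sub>ROH</sub> + 20 GRM PCs + SNP missingness + excess heterozygosity + dataset fixed effects,

so a slope β (on the 0–1 proportion scale) means a
100·(e^(β/100) − 1) % change in the odds of disease per additional 1% of
the genome autozygous — β = 16.1 ⇒ ≈ +17%. Because *F*<sub>ROH</sub> varies
far more *between* recruitment sites than genotype frequencies do, this
design is exquisitely sensitive to site-level ascertainment differences;
the package includes the whole-site label-flip permutation null that
makes the resulting type-I inflation measurable.

What it provides, per module:

* **IO** — PLINK text `.ped/.map` (read/write), VCF 4.x with GT (read),
  PLINK-style `.hom`/`.hom.indiv` (write/read back), TSV tables.
* **QC** — exact Hardy-Weinberg test, sample missingness/heterozygosity/
  relatedness filters, SNP missingness and differential-missingness
  filters, VIF sliding-window LD pruning.
* **ROH calling** — ≥40 consecutive homozygous SNPs, no heterozygotes,
  density > 1 SNP/200 kb, 500 kb gap splitting; threshold re-filtering
  over 40–200 SNP and 1–20 Mb grids; longest-ROH and >30 Mb sensitivity
  filters.
* **Autozygosity** — *F*<sub>ROH</sub>, short/long decomposition at 8 Mb
  (with the variance-equalizing cutoff search), per-dataset descriptives.
* **Association** — GRM, ancestry PCs, in-package IRLS logistic fits
  (verified against `glm()`), threshold sweeps, per-dataset and pooled
  fits, stratum-by-*F*<sub>ROH</sub> interaction test.
* **Null experiments** — site-flip permutation null and power simulation.
* **Synthetic cohorts** — multi-site generator with planted IBD segments,
  logistic liability on true *F*<sub>ROH</sub>, and site-level
  ascertainment confounding (per-site case-control *F*<sub>ROH</sub>
  shifts).

## Worked example

A complete run on a bundled synthetic cohort (3 sites, 500 samples,
scaled-down 2×10⁸ bp genome, true slope β = 16.1):

```r
library(rohburden)
res <- demo_pipeline(seed = 1)
print(res)
#> ROH burden pipeline result
#>   samples: 500   pruned SNPs: 7998
#>   analysis thresholds: 60 SNPs / 2 Mb
#>   pooled fit: Froh burden fit [pooled]
#>   beta = 22.4  (95% CI 2.73, 42)  z = 2.23  p = 0.0256
#>   odds change per +1% Froh: +25.08%
#>   n = 500
```

The pooled covariate-adjusted fit recovers a positive slope whose 95% CI
covers the planted β = 16.1: at this sample size the odds of "disease"
rise significantly with each percent of the genome autozygous. Per-site
descriptives (the `avg_froh_x100` column is *F*<sub>ROH</sub>×100, i.e.
percent of genome):

```r
res$descriptives
#>   dataset_id   n n_cases avg_froh_x100 sd_froh_x100   avg_mb    sd_mb
#> 1      siteA 180      90     0.9984183     1.766558 3.020425 1.637723
#> 2      siteB 170      80     0.7990535     1.697505 2.985474 1.246816
#> 3      siteC 150      70     0.9184907     1.775629 2.995078 1.420530
```

and the short/long decomposition at the 8 Mb cutoff:

```r
print(res$fit_short)
#> Froh burden fit [froh_short]
#>   beta = 21.5  (95% CI 2.36, 40.6)  z = 2.2  p = 0.0276
#>   odds change per +1% Froh: +23.95%
#>   n = 500
```

The demo plants most autozygosity in sub-8 Mb segments, so the signal
concentrates in *F*<sub>ROH-short</sub> while the long component is noise
— the same decomposition the full-scale analysis reports.

The headline closed-form anchors:

```r
or_per_percent(16.1)   # 17.4685  -> "approximately 17%"
wald_p(3.44)           # 0.000582 -> prints as 0.0006
```

And the confounding demonstration (17 sites, site-level *F*<sub>ROH</sub>
shifts of SD 0.001 — a fifth of the *F*<sub>ROH</sub> SD — with no true
effect):

```r
sp  <- cohort_spec(site_sizes = default_site_sizes(),
                   beta_true = 0, confound_tau = 0.001, seed = 7)
sk  <- simulate_froh_cohort(sp)
dm  <- model.matrix(~ factor(sk$dataset_id))[, -1]
site_flip_permutation(sk$phenotype, sk$f_target, dm,
                      sk$dataset_id, n_perm = 500, seed = 8)
```

reports an empirical type-I error far above the nominal 0.05 — the
mechanism by which random per-site ascertainment bias manufactures
spurious "significant" burden associations.

## Command line

```sh
Rscript -e 'rohburden::roh_burden_cli()' demo --seed 1 --out out/
Rscript -e 'rohburden::roh_burden_cli()' run --config cohort.json --out out/
Rscript -e 'rohburden::roh_burden_cli()' permute --config cohort.json --n-perm 500 --seed 1
```

See `vignettes/roh-burden-methods.Rmd` for the model, the generator's
stated world and its limits, and every numerical convention.
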