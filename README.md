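# geostrat

Population structure and batch effects in rare-variant case-control
studies, as a reusable, tested R pipeline.

Whole-genome sequencing studies of diseases like ALS face two analytic
hazards that barely affect common-variant GWAS. First, rare variants
cluster geographically at very fine scales, so imperfect geographic
matching of cases and controls can inflate genic burden tests. Second,
"free" controls sequenced by another project carry platform-specific
genotype artifacts, so merging them at the VCF level manufactures
association signal out of calling differences. `geostrat` provides the
machinery to study both effects quantitatively: a synthetic-cohort
generator with the relevant spatial statistical structure, and every
analysis stage such a study runs on real data.

Because individual-level data of the studies this emulates are
access-controlled, the generator is a first-class, tested component: all
analyses are demonstrated and validated on cohorts whose structure is
known by construction.

## What is implemented

**Synthetic cohorts** (`simulate_cohort`, `simulate_study`) — a 2:1
case-control cohort on a rectangular map (default approximates the
Netherlands):

* common variants with smooth allele-frequency clines:
  `p_local = logit^-1(logit(p0) + c * z)` with `z` the standardized
  projection of birthplace on a random direction;
* rare variants (cohort MAF < 0.5%) whose carriers are sampled with
  probability `exp(-d_km / kernel)` around a random origin — tight
  spatial clustering;
* pairwise IBD segments, Poisson with mean `a * exp(-d_km / rho) + b`
  per length bin (1–2, 2–7, 7–15 cM), `rho` shrinking with segment
  length;
* case/control labels under perfect matching or a configurable
  North-to-South case gradient;
* an externally sequenced control cohort: same population, re-measured
  with per-site allele-flip/missingness errors at a fraction of sites.

**Analysis stages**

| stage | functions |
|---|---|
| genotype I/O (VCF v4.2 GT-only, sample sheet, gene groups, IBD table) | `read_vcf`, `write_vcf`, `load_cohort`, ... |
| QC (call rate, het outliers, relatedness, exact HWE in controls) | `run_sample_qc`, `run_variant_qc`, `hwe_exact_test` |
| GRM / PCA / birthplace prediction | `compute_grm`, `pca`, `predict_birthplace_loo`, `variance_explained` |
| IBD vs distance | `ibd_distance_summary` |
| single-variant association | `fit_null_logistic`, `score_test_variant`, `gw_scan`, `genomic_lambda` |
| genic burden tests (T1, T5, Madsen–Browning, Variable Threshold, SKAT) | `build_groups`, `run_burden_scan`, ... |
| FWER calibration by phenotype simulation | `simulate_null_replicates`, `minima_per_replicate`, `fwer_threshold`, `calibrate_fwer` |
| external-control merge experiment | `merge_cohorts`, `freq_diff_filter`, `assess_separation`, `external_control_scan` |

All burden tests share one covariate-adjusted score framework: with null
fit `ŷ` and `W = diag(ŷ(1-ŷ))`, a burden vector `b` is tested by
`U = b'(y-ŷ)`, `V = b'Wb - b'WX (X'WX)^-1 X'Wb`, `U²/V ~ χ²₁`. T1/T5
collapse dosages below a MAF cutoff; MB weights by
`1/sqrt(n_ctrl q(1-q))` with `q` the smoothed control frequency; VT
maximizes `|U_t|/sqrt(V_t)` over observed MAF thresholds with a
residual-permutation p-value; SKAT uses
`Q = (y-ŷ)' G W² G' (y-ŷ)` with a `Σ λ_l χ²₁` null evaluated by
characteristic-function inversion (Liu moment-matching fallback).

## Worked example

```r
library(geostrat)

study <- simulate_study(sim_config(seed = 1))   # 400 cases, 200 controls,
co <- study$internal                            # 2000 common + 5000 rare
qc <- run_variant_qc(run_sample_qc(co)$cohort)$cohort

pc <- pca(compute_grm(qc, maf_min = 0.001), k = 20)
variance_explained(pc$vectors[, 1], qc$samples$lat)  # PC1 vs latitude
for (t in c(0.1, 0.001)) {
  p <- pca(compute_grm(qc, maf_min = t), k = 20)
  print(predict_birthplace_loo(p, qc$samples[, c("lat","lon")])$median_error_km)
}

mg  <- merge_cohorts(qc, study$external)$cohort
sc  <- external_control_scan(mg)
cal <- calibrate_fwer(qc, n_rounds = 6, seed = 99)
```

Output on this machine:

```
QC-passing: 597 samples x 6256 variants
PC1 explains 62% of latitude variance (p = 1.2e-126)
median LOO birthplace error (MAF >= 0.1):   61.3 km
median LOO birthplace error (MAF >= 0.001): 47.9 km
external merge: PC1|cohort separation 0.90, lambda single 1.78, lambda burden 15.96
FWER threshold (5th of 100 minima): 3.40e-04; achieved FWER 4.5%
bonferroni exome-wide: 5e-07
```

Reading this: the first principal component of the genetic relationship
matrix recovers latitude; birthplace prediction from 20 PCs sharpens when
rarer variants enter the GRM (61 → 48 km median error), the signature of
fine-scale rare-variant clustering. Naively merging the externally
sequenced controls makes PC1 a batch axis (|r| = 0.90 with cohort label)
and inflates the case-vs-external scan (λ = 1.78 single-variant, far
worse for burden tests), while the perfectly matched design keeps the
study-wise type-I error of the fifth-order-statistic threshold rule at
its nominal 5%.

## Command line

```sh
GS=$(Rscript -e 'cat(system.file("cli/geostrat.R", package = "geostrat"))')
Rscript $GS simulate --out sim --seed 11
Rscript $GS qc --vcf sim/cohort.vcf --samples sim/samples.tsv --out qc
Rscript $GS predict-birthplace --vcf qc/qc_passed.vcf --samples qc/qc_passed_samples.tsv
Rscript $GS burden --vcf qc/qc_passed.vcf --samples qc/qc_passed_samples.tsv \
        --groups sim/groups.tsv --out burden
Rscript $GS merge-external --cases qc/qc_passed.vcf \
        --cases-samples qc/qc_passed_samples.tsv --groups sim/groups.tsv \
        --external sim/external.vcf --external-samples sim/external_samples.tsv
Rscript $GS run-all --out full_run --seed 1     # entire pipeline + manifest
```

## Vignette

`vignettes/geostrat-methods.Rmd` documents the statistical model behind
the generator, every tunable parameter with its default and rationale,
numerical choices (SKAT tail evaluation, eigenvector sign convention,
tie-breaks in QC), and what the synthetic world does and does not
establish about real data.
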