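---
title: "geostrat: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{geostrat: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(geostrat)
```

`geostrat` studies two failure modes of sequencing-based case-control
studies — fine-scale population stratification of rare variants, and
batch artifacts from externally sequenced controls — on synthetic cohorts
whose structure is known by construction. This vignette is the package's
account of its models and the choices behind them. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The synthetic world

All randomness descends from one master seed through named substreams
(`substream_seed`), so any stage can be regenerated independently and
every output is reproducible from configuration plus seed.

### Geography

Individuals are born uniformly in a rectangular box, by default
[50.7, 53.5] degrees latitude by [3.3, 7.2] degrees longitude — a
rectangular approximation of the Netherlands. Only relative geometry
matters downstream; distances use the haversine formula with Earth
radius 6371.0 km, and local planar kilometre coordinates are used where a
Euclidean projection is convenient (kernel distances, cline directions).
The box, not the coastline, is deliberate: coastline realism would add
code without changing any statistical property under test.

### Common variants

Each of `n_common_variants` (default 2000) variants draws a baseline
frequency `p0 ~ U(0.05, 0.5)` and a uniformly random planar direction;
the local allele frequency for an individual at standardized projection
`z` along that direction is `plogis(qlogis(p0) + cline_strength * z)`,
and genotypes are two Bernoulli draws at the local frequency. Setting
`cline_strength = 0` recovers exact Hardy–Weinberg sampling at `p0` (a
tested limit).

`cline_strength` defaults to **0.1**. This was calibrated once, before
any acceptance test existed, against the geographic structure the
package is meant to emulate: at 0.1 the first GRM principal component
explains roughly 60–75% of latitude variance on a 600-sample cohort and
the median leave-one-out birthplace error falls from ~60 km (common
variants only, MAF ≥ 0.1) to ~45 km when rare variants enter (MAF ≥
0.001) — the same qualitative regime as the 50 km → 36 km sharpening
reported for real Dutch genomes. Larger values (≥ 0.3) make geography
essentially noiseless (PC R² > 0.95, LOO errors < 20 km), which is
unrealistically strong for a country-scale cohort at this variant count.

One consequence worth knowing: because all variants share the same 2-D
geographic factor, single-variant test statistics are positively
correlated across the genome even under perfect matching. At 2000
variants the genomic inflation factor of a perfectly matched scan
therefore fluctuates cohort-to-cohort with a standard deviation near
0.07 — much more than the i.i.d. expectation. A λ of 1.1 on one seed and
0.91 on another are both "calibrated" at this desk scale.

### Rare variants

Each of `n_rare_variants` (default 5000) variants originates at the
birthplace of a randomly chosen individual. A carrier count is drawn
from a truncated geometric on {1..10} with success probability 0.5
(mean ≈ 2, so most variants have fewer than three allele observations,
matching the observed skew of deep-sequenced cohorts), and is further
capped so the cohort MAF stays strictly below 0.005; at 600 samples the
two constraints conflict (10 heterozygous carriers would be MAF 0.0083),
and the MAF bound wins because it is the generator's contract. Carriers
are drawn without replacement with weight `exp(-d_km /
rare_kernel_scale_km)` from the origin and made heterozygous.
`rare_kernel_scale_km` defaults to 20 km — village-to-town scale
clustering, the regime in which rare alleles are shared by birthplace
neighbours; there is no published value for this kernel, so it is a
package choice, exposed in the configuration. As the kernel goes to
infinity carriers become exchangeable (a tested limit).

Rare variants are partitioned evenly into `n_genes` (default 200) genes
and labelled LOF / nonsynonymous / other with probabilities 0.15 / 0.55
/ 0.30 — the rough class mix of coding annotation, with "other" excluded
from burden groups.

### Phenotypes and matching scenarios

`perfect` draws exactly `n_cases` cases uniformly without replacement —
geography-blind labels. `imperfect` weights case sampling linearly in
latitude so the southern map edge carries `1 + gradient_strength` times
the weight of the northern edge, with the count held fixed. The gradient
points south by default and its magnitude (default 2, i.e. a 3:1 weight
ratio) is a package choice: the real study's supplementary gradient is
not quantified in its main text, so the sign is configurable and the
default is strong enough that a 600-sample cohort shows a clearly
significant case/control latitude difference in ~every replicate.

### IBD segments

For every unordered pair and every length bin the shared-segment count
is Poisson with mean `a * exp(-d_km / rho) + b`. Defaults per bin
(1–2, 2–7, 7–15 cM): `a` = 0.6, 0.5, 0.35; `rho` = 400, 150, 60 km;
`b` = 1.2, 0.15, 0.01. Short (old) segments are ubiquitous and nearly
distance-flat; long (recent) segments are rare and sharply
distance-bound — the qualitative pattern seen in Dutch data. The
constants are order-of-magnitude choices, not fits; the analyses
consume only the monotone structure. Phasing and segment detection are
out of scope: segments are simulated directly, not inferred from
genotypes.

### The external cohort

`simulate_study` draws one population of
`n_cases + n_controls + n_external_controls` individuals (shared variant
definitions and frequency surfaces), splits off the last
`n_external_controls` (default 200) as a control-only cohort, and
re-measures it with the platform error model: a fraction
`batch_site_fraction` (default 0.3) of sites is affected; at those sites
each genotype independently flips one allele (hom→het, het→either hom)
with probability `batch_error_rate` (default 0.02) or is set missing
with probability half that. The model operates on genotypes, not reads,
because the experiment it feeds merges cohorts "at the VCF level";
genotype-space is the faithful abstraction of calling differences.

The quantitatively important consequence is at rare sites: a 2%
per-genotype flip rate creates ~4 spurious carriers per 200 external
samples at an affected site whose true carrier count is ~2 in 600 —
a huge relative distortion, which is why burden tests (aggregating many
rare sites) inflate far more than single-variant scans, and why the >5%
absolute frequency-difference filter, which operates at common-variant
scale, barely touches the burden inflation. This asymmetry is the
mechanism behind the real-data observation that burden λ (2.49) vastly
exceeded single-variant λ (1.12) with external controls; at desk scale
the package reproduces the ordering, not the values.

## 2. Analysis-stage choices

**Dosage convention.** Genotypes are stored as minor-allele dosage with
the minor allele decided per site in the loaded cohort (ties keep ALT);
the `minor_allele` column preserves orientation so that merging two
cohorts can re-align flipped sites by REF/ALT identity.

**QC.** Defaults: 95% call rate at both levels, ±3 SD heterozygosity
outliers, exact HWE in controls at p < 1e-6 (controls only, since case
genotypes may legitimately deviate), relatedness pruning at kinship
0.0884 (3rd-degree cutoff). The relatedness rule compares GRM
off-diagonal / 2 against the kinship threshold: GRM entries are about
twice the kinship coefficient, and at desk-scale variant counts
(M ≈ 1-2k, entry noise sd ≈ 1/sqrt(M) ≈ 0.03) thresholding raw GRM
entries at 0.0884 would falsely prune several unrelated pairs per
cohort. The relatedness GRM uses common variants only (MAF ≥ 0.05):
rare-variant contributions to GRM entries are heavy-tailed (two carriers
of one rare variant contribute ~1/(2·MAF·M)) and would break any fixed
threshold. The exact HWE test enumerates all heterozygote counts
conditional on allele counts and sums probabilities no larger than the
observed configuration's (no mid-p).

**Null model and score tests.** The logistic null is fitted by plain
Newton/IRLS to a score-norm tolerance of 1e-8 (max 50 iterations);
separation is flagged when fitted log-odds exceed ±15 — a coefficient
cap proved wrong because near-collinear covariates produce legitimately
huge coefficients with bounded fitted values. Every association and
burden statistic is an efficient score test against this null: the
shared machinery is what makes T1/T5/MB/VT and the single-variant scan
mutually consistent (several acceptance identities depend on it), and a
score test needs only one null fit per phenotype, which is what makes
the 600-replicate calibration loop cheap. Missing genotypes are
mean-imputed per variant for testing.

**SKAT.** Weights default to the Beta(1, 25) density at the variant MAF;
the mixture-of-χ² tail is evaluated by numerical inversion of the
characteristic function (Imhof-type integrand via `integrate`), with the
Liu et al. moment-matching non-central-χ² approximation as fallback when
the quadrature fails or leaves (0, 1]. The quadrature is accurate to
about 1e-4 absolute, so identity tests against the score test use a
5e-3 tolerance. The two evaluations agree within 10% relative for
p > 1e-4 on random mixtures (a tested property).

**Variable threshold.** Candidate thresholds are the distinct member
MAFs; burdens accumulate variants with MAF ≤ t. The permutation scheme
permutes null-model residuals rather than raw phenotypes so the
covariate adjustment is respected; `V_t` is permutation-invariant, so
only `U_t` is recomputed, making B = 1000 (200 inside simulation loops)
cheap. The permutation p-value is `(1 + #{perm ≥ obs})/(B + 1)`,
bounded below by 1/(B+1).

**Madsen–Browning.** Implemented as a weighted score test (weights
`1/sqrt(n_ctrl q(1-q))`, `q` the +1-smoothed control frequency), not the
original rank-sum permutation form: covariate adjustment requires the
regression framework, and constant weights provably reduce it to the
plain collapse test (tested identity).

**Birthplace prediction.** Latitude and longitude are regressed
separately on the top 20 PCs with intercept; the leave-one-out
prediction uses the exact hat-matrix identity
`fit_i - h_ii e_i / (1 - h_ii)`, algebraically identical to refitting
without sample i (tested against the literal refit). Only the
regression is refitted, not the PCA: the leave-one-out is tied to the
linear model. Recomputing the PCA per holdout would leak no information
either way here, because the coordinates play no role in the GRM.

**Eigen conventions.** Eigenvectors are sign-fixed (largest-magnitude
loading positive) for cross-platform reproducibility; eigenvalues are
non-increasing; orthonormality is asserted to 1e-8 in tests.

**FWER calibration.** The threshold is the k-th smallest of the
per-replicate minimum p-values with `k = max(1, floor(alpha n))` — the
"fifth-most extreme of 100" rule at the defaults. Minima are taken over
the LOF and nonsynonymous groups. Two numerical notes. First, at desk
scale the minima distribution has an atomic lower tail (an intercept-only
score test p depends only on the discrete carrier/case overlap), which
biases the achieved error rate a little below the nominal `k/(n+1)` and
makes it less variable than the continuous Beta(k, n+1-k) theory
predicts. Second, a single draw of the procedure still has a standard
deviation near 2 percentage points, so `calibrate_fwer(n_rounds = )`
supports averaging several independent calibration→evaluation rounds;
`scripts/acceptance.R` uses 6 rounds, estimating the same operating
characteristic with ~1-point noise. Common-variant PCs (MAF > 0.001),
when used as covariates, are computed once per cohort, not per
replicate: phenotypes change, genotypes do not.

**Merge experiment.** Site-intersection merge (not union-with-missing):
union would confound batch missingness with the frequency filter, while
intersection isolates the calling-difference effect under study. The
frequency filter compares each cohort's frequency of the first cohort's
minor allele; the separation metric is the absolute point-biserial
correlation of PC1 with cohort membership, computed on a low-MAF GRM
(floor 0.001) because the batch signal lives disproportionately at rare,
flip-sensitive sites.

## 3. What a green test establishes — and what it does not

The generator reproduces the *statistical skeleton* the analyses assume:
frequency-stratified spatial clustering, distance-decaying IBD, a
case-gradient scenario, and genotype-level batch error. It does not
simulate linkage disequilibrium, coalescent genealogies, realistic site
frequency spectra, sequence content, read-level error, or missingness
that correlates with depth. Consequently green tests establish that the
*methods* behave correctly (calibrated nulls, correct oracles, right
directional responses to planted structure), not that any particular
real-data number is recoverable. The headline real-data values (λ =
1.12/2.49, 55%/24% variance explained, 50→36 km, the Table-2 thresholds)
depend on access-controlled genomes and are replaced throughout by
directional properties at desk scale, plus the two printed-number
targets that are scale-free (the 5e-7 exome-wide Bonferroni threshold
and the 5% achieved FWER of the order-statistic rule).

Known limitations, in one place: desk-scale λ is noisy (see above);
VT p-values inside simulation loops are resolution-limited below
1/(B+1) = 1/201; the HWE filter also removes strongly clined variants
(Wahlund effect), which is faithful to practice but means variant QC is
not structure-neutral; and `simulate_study`'s external cohort can
slightly exceed the rare-MAF cap within its own 200 samples (the cap is
enforced for the internal cohort, whose invariant it is).
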