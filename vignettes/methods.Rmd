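---
title: "Methods: temporal phenomics, FPCA and multikernel prediction in phenomGP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal phenomics, FPCA and multikernel prediction in phenomGP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind `phenomGP`, the
choices that were genuinely open when the package was designed, and
what its synthetic-data validation does and does not demonstrate about
real field data.

## 1. Stage-1 mixed models

Every analysis is fitted separately per population and environment
(year/trial). For an end-of-season trait (grain yield in t/ha, plant
height in cm) on a randomized complete block design with a range-by-row
grid and `r` replications:

    Y_ijkl = mu + H_i + Range_j + Row_k + Rep_l + e_ijkl

`fit_blues()` treats the hybrid effect `H_i` as fixed and the design
terms as random, and reports the BLUE of each hybrid on the trait
scale. Whether the design terms are fixed or random is not dictated by
the model statement; we treat them as random, which is standard for
multi-hybrid yield trials where range and row act as nuisance strata
with many levels and few observations each. `estimate_heritability()`
refits the same model with *all* terms random and reports the
entry-mean heritability

    h2 = s2_H / (s2_H + s2_e / r),

deliberately excluding the range/row/rep variances from the
denominator: the design variances are removable by blocking and do not
dilute hybrid-mean comparisons. For each vegetation index the temporal
model

    V_ijklm = mu + H_i + F_j + (HF)_ij + Range_k + Row_l + Rep_m + e

is fitted fully random; `fit_temporal_blups()` returns the
hybrid-by-flight interaction BLUPs `(HF)_ij` on the complete
hybrid-by-flight grid (missing cells shrink to zero), plus the hybrid
main-effect BLUP `H_i` in a separate column.

**Estimation engine.** Variance components are estimated by REML with
`lme4::lmer`; BLUEs and BLUPs are then by construction the
GLS/Henderson mixed-model-equation solutions at the converged
variances. The test suite verifies this equivalence against a dense,
independently coded Henderson-MME and GLS oracle (agreement to 1e-6 on
small instances) and verifies that the REML criterion at the returned
variances beats a brute-force variance grid. Within an environment all
36 VIs share one design, so after the first fit the remaining indices
are refitted on the same factorization (`lme4::refit`), which keeps the
most expensive stage (36 indices x up to 20 flights x 830 plots) at a
few minutes.

Degenerate inputs are handled before the optimizer sees them: constant
responses return zero variances directly; noise-free data (zero
within-hybrid variance) return replicate means as BLUEs and
heritability 1; random terms with fewer than two observed levels are
dropped because their variance is not identifiable.

## 2. Temporal correlations

`temporal_correlation()` computes, per flight, the Pearson correlation
over hybrids between the hybrid's temporal value and its trait BLUE,
and summarizes flights by mean and SD. Pearson correlation is used
throughout (prediction abilities are Pearson correlations too, so the
scales match).

The temporal value used here is `H_i + (HF)_ij`, the hybrid's full
predicted deviation at a flight — not the interaction BLUP alone. This
was a genuinely open choice, and the interaction-only variant is
provably degenerate for this purpose: interaction BLUPs are
mean-centered within hybrid, so the per-flight correlation profile of
any single genetic driver must change sign across the season and its
flight-mean is forced toward zero no matter how strongly the VI's
genetics align with yield. Including the hybrid main effect restores
the quantity of interest ("do hybrids that are greener at flight t
yield more?"). Flights with zero variance in either variable have no
defined correlation and are excluded from the summary (not set to 0),
with a warning. `rank_vis()` orders indices by mean correlation with
ties broken alphabetically, and its top index is the natural secondary
trait for the multitrait model.

## 3. FPCA of temporal curves

Stage-1 BLUP curves live on a common, dense, environment-specific DAP
grid, so the Karhunen-Loeve decomposition

    V_i(t) = mu(t) + sum_k xi_ik phi_k(t)

is computed exactly at the observed design: trapezoid quadrature
weights `w` on the DAP grid, eigendecomposition of `W^(1/2) S W^(1/2)`
with `S` the sample covariance of curves, eigenfunctions
`phi = W^(-1/2) v` (orthonormal in the weighted inner product), scores
as weighted inner products of centered curves with eigenfunctions. A
sparse-design estimator (PACE-style conditional expectation, with its
bandwidth and fraction-of-variance options) would reduce to this in the
dense case while adding unanchored smoothing choices; with 5–20 flights
per environment we therefore do not pre-smooth. Eigenfunction signs are
fixed by making each function's largest-magnitude grid value positive,
so repeated fits give identical scores. All components are retained
internally; downstream analyses use the first two scores per VI.

Two flight windows are analyzed: *until flowering* (flights with DAP at
or before the environment's flowering start, inclusive) and *full* (all
flights). `build_score_matrix()` emits one row per hybrid and two
columns per VI (`<VI>.FPCA1`, `<VI>.FPCA2`) in canonical alphabetical
VI order; because the column labels do not mention flight dates,
`merge_environments()` concatenates score matrices row-wise across
environments with arbitrary flight schedules — this is the step that
makes cross-year phenomic prediction possible.

Validation: on constructed rank-1 curves the first eigenfunction is
recovered with weighted cosine similarity > 0.99 and scores correlate
with truth at |r| > 0.99; the eigenvalue sum equals the
quadrature-integrated pointwise variance to 1e-8; centered curves are
reconstructed exactly from the full basis.

## 4. Relationship kernels

With `X` the hybrids-by-markers 0/1/2 matrix, columns centered and
standardized (population denominator, monomorphic markers dropped), the
genomic kernel is `G = X_c X_c' / p`, so `trace(G)/n = 1` exactly. The
phenomic kernel applies the same construction to the FPCA score
columns, `P = R_c R_c' / (2 x 36)` (divisor reduced if constant columns
are dropped). Standardizing the score columns before `RR'` was an open
choice — only the divisor is canonical — and we standardize because raw
FPCA scores have wildly different scales across VIs, which would let a
handful of high-variance indices dominate the kernel; after
standardization `trace(P)/n = 1`, putting genomic and phenomic variance
components on the same scale.

The environment term is a random effect with covariance
`Z_E Z_E' / n_env` (records in the same environment covary at
`1/n_env`), not a fixed mean: the kernel form is explicitly a
covariance, and a random environment effect lets the leave-one-out
scenarios shrink rather than extrapolate environment means.
Interactions follow the reaction-norm construction: Hadamard products
of the unscaled same-environment indicator with the record-expanded
genomic (or phenomic) kernel, divided by `n_env` (or
`n_env x 36 x 2`). All kernels are symmetrized; eigenvalues below
`1e-8 x max` are truncated before sampling, which also clips
floating-point negatives.

## 5. Bayesian kernel regression

Models M1–M5 are Gaussian kernel regressions
`y = mu + sum_k u_k + e`, `u_k ~ N(0, K_k s2_k)`, fitted by Gibbs
sampling. Each kernel is eigendecomposed, `K = V D V'`, and the effect
reparameterized as `u = V D^(1/2) alpha` with `alpha ~ N(0, I s2_k)`;
since `(V D^(1/2))' (V D^(1/2)) = D` is diagonal, the whole coefficient
block has a closed-form conditional posterior and is sampled jointly —
no coordinate loops, so chains are fast and mix well. Variances carry
scaled-inverse-chi-square priors with `df0 = 5` and scales that split a
prior R² of 0.5 equally across the non-residual terms (each divided by
the kernel's mean diagonal); the residual gets the remaining half.
Records with missing responses are sampled by data augmentation, which
is precisely how untested hybrids and held-out environments receive
predictions. Defaults are 12,000 iterations, 2,000 burn-in, thinning 5;
the cross-validation helpers use shorter, validated chains. Chains are
bit-reproducible for a fixed seed, and each CV fit derives a distinct
seed from the configuration.

M6 is the bivariate multitrait variant: the response pairs the trait
with the VARI FPCA1 score (secondary trait, observed for every record).
The genomic and genomic-by-environment terms carry unstructured 2x2
covariance matrices with inverse-Wishart priors; the environment term
stays trait-specific independent (its rank is the number of
environments, far too low to inform a cross-trait covariance); the
residual covariance is unstructured. Missing primary values are imputed
from their conditional normal given the secondary trait, which is the
mechanism by which drone data sharpens predictions for unphenotyped
records. Where the 2x2 covariances sit was open; placing them on the
genetic terms and the residual is the minimal structure that produces
the multitrait borrowing the model exists for. Validation: the sampler
recovers a simulated genetic correlation of 0.8 within 0.15, matches
conjugate closed-form posterior means when the variances are pinned by
an overwhelming prior, and beats the univariate model on masked records
when traits share genetics.

## 6. Cross-validation scenarios

Folds are hybrid-level (5 folds, sizes differing by at most one): a
hybrid is tested or untested consistently across environments within a
repeat, and the same fold plan drives all four scenarios. CV2/CV1 train
on tested hybrids' records from all environments — untested hybrids'
responses are withheld everywhere — and score tested (CV2) and untested
(CV1) hybrids per environment. CV0/CV00 hold one environment out
entirely, train on tested hybrids in the remaining environments, and
score tested (CV0) and untested (CV00) hybrids in the held-out
environment; every environment serves once as held-out. The M6
secondary trait remains observed in all scenarios, including held-out
environments — drone data are cheap to collect on untested material,
which is the premise of the design. Summaries report mean ± SD of
prediction ability pooled over environments, repeats and folds (which
of these the reference summaries pool over is not stated anywhere; we
pool all three and say so).

## 7. The synthetic-trial generator

`simulate_trial()` is the package's test bed and defines the study
conditions. Genetic values are marker-determined (`u = X beta`,
rescaled to a genetic SD of 0.8 t/ha for yield and 10 cm for height),
so genomic kernels carry real signal; per-environment GxE deviations
are Gaussian with variance a configurable fraction (default 0.3) of
genetic variance. VI trajectories are double-logistic (green-up rise,
flowering plateau, senescence decline); hybrid genetics enter the curve
baseline, the amplitude, and the green-up timing through a
VI-specific loading on a shared driver `z` built to correlate with the
yield genetic value at `vi_genetic_corr` (default 0.5). VARI gets
loading +1 and RCC −1, reproducing their empirically strongest
positive/negative temporal correlations. The baseline term matters: it
is what makes per-flight correlations one-signed across the season, as
observed for VARI, rather than sign-flipping. Default entry-mean
heritabilities (0.55 yield, 0.65 height) sit inside the ranges typical
of temperate maize hybrid trials (roughly 0.2–0.7 for yield, 0.4–0.8
for height); residual variances are derived from the
target heritability via the entry-mean formula, counting the
within-environment hybrid variance (main + GxE). Preset configurations
mirror the study shapes: `pop1` (415 hybrids; 7- and 14-flight
environments) and `pop2` (220 hybrids; 17-, 17- and 20-flight
environments), with flowering inside each flight window.

What the generator does *not* emulate: spatial autocorrelation (range
and row effects are independent Gaussians, matching the additive model
actually fitted), linkage disequilibrium between markers (markers are
independent binomials, so genomic prediction accuracy for untested
hybrids is conservative relative to real maize panels, where LD lowers
the effective marker dimension), dominance (top-cross hybrids do not
permit estimating it), weather-driven trajectory shapes, and image
noise. Passing tests therefore demonstrate the correctness and internal
consistency of the estimators under the assumed generative family — not
that real-data accuracies will match any particular value.

## 8. Problem sizes and numerical settings

The test suite and the acceptance script run at desk scale, chosen so
the full suite completes in minutes while each assertion remains
statistically meaningful: bookkeeping runs use the full preset shapes
(415/220 hybrids, 36 VIs, all flights); parameter-recovery runs use
300–800 records with 10–20 seeds; cross-validation properties use
100-hybrid trials, 5 folds and 2 repeats with 1,500–3,000 Gibbs
iterations (orderings at these settings are stable across seeds; the
package defaults remain 12,000/2,000/5 for final analyses; 20 CV
repeats are available via configuration). REML convergence follows
lme4's deviance-based criterion; variance grids in the tests bracket
the optimum to 1e-6.

## 9. Known limitations

* Genomic and genomic-by-environment variance components are only
  weakly separated when the relationship matrix is near-identity (few
  hybrids, independent markers); their sum and the residual are well
  identified, and the tests assert exactly that.
* The environment variance is estimated from as many effective
  observations as there are environments (2–3); its posterior is
  prior-dominated and should not be interpreted.
* Temporal correlations and FPCA are computed per environment and make
  no attempt to register curves in time; environments with very
  different phenology enter the merged score matrix unaligned, by
  design.
* The Gibbs samplers assume Gaussian responses; heavy-tailed traits
  would need a different residual model.
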