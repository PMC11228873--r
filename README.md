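# phenomGP

Phenomic and genomic prediction of maize grain yield and plant height
from temporal drone-derived vegetation indices, across years and trials
whose drone flights never line up.

## The problem

Field-based high-throughput phenotyping yields, for every plot, a time
series of vegetation indices (VIs) — 33 RGB indices such as VARI and RCC
plus the raw R, G, B band means (36 features) — measured at irregular
flight dates (days after planting, DAP). These biomarkers are cheap,
heritable, and correlated with end-of-season grain yield (t/ha) and
plant height (cm), which makes them attractive predictors for hybrids
or environments that have no trait records yet. The obstacle is that
flight schedules differ between years and trials, so the temporal
feature vectors cannot be column-bound across environments.

`phenomGP` implements a two-stage pipeline that removes this obstacle:

1. **Stage 1 — per-environment mixed models (REML).** For each trait,
   `Y = mu + Hybrid + Range + Row + Rep + e` gives hybrid BLUEs and the
   entry-mean heritability `h2 = s2_H / (s2_H + s2_e / r)` with `r`
   replications. For each VI,
   `V = mu + Hybrid + Flight + Hybrid:Flight + Range + Row + Rep + e`
   (all terms random) gives the hybrid-by-flight BLUPs — the hybrid's
   temporal deviation curve on that environment's flight grid.

2. **Stage 2 — FPCA and kernel prediction.** Functional principal
   component analysis of the BLUP curves, `V_i(t) = mu(t) + sum_k xi_ik
   phi_k(t)`, summarizes each hybrid-by-VI curve by its first two scores
   (FPCA1, FPCA2) under two flight windows: flights until flowering and
   all flights. Score columns have identical names in every environment,
   so per-environment score matrices merge row-wise regardless of flight
   dates. From the merged scores and the marker matrix the package
   builds relationship kernels — genomic `G = XX'/p`, phenomic
   `P = RR'/(2x36)`, environment `Z_E Z_E'/n_env`, and Hadamard
   reaction-norm interactions `gxE`, `PxE` — and fits six Bayesian
   kernel regression models by Gibbs sampling:

   | model | response | kernels |
   |-------|----------|---------|
   | M1 | trait | E, g, gxE |
   | M2 | trait | E, P1, P1xE |
   | M3 | trait | E, P2, P2xE |
   | M4 | trait | E, g, P1, gxE, P1xE |
   | M5 | trait | E, g, P2, gxE, P2xE |
   | M6 | trait + VARI FPCA1 (bivariate) | E, g, gxE |

   P1 uses the until-flowering window, P2 all flights; M6 is a
   multitrait model whose secondary trait (the VARI FPCA1 score, chosen
   because VARI shows the strongest positive temporal correlation with
   yield) stays observed for all records.

Four cross-validation scenarios mirror breeding use cases: CV2/CV1
score tested/untested hybrids in observed environments; CV0/CV00 score
tested/untested hybrids in a held-out environment
(leave-one-environment-out). Prediction ability is the Pearson
correlation between predictions and BLUEs.

Real multi-environment trial data are large and rarely redistributable,
so the package includes a first-class synthetic-trial generator
(`simulate_trial()`) that emulates the target design — two hybrid
populations (415 and 220 hybrids), RCBD with 2 replications, 7–20
flights per environment on mismatched DAP grids, double-logistic VI
trajectories whose genetics are correlated with yield — and records the
ground truth, so every stage is verifiable end to end.

## Worked example

```r
library(phenomGP)

cfg <- sim_config(
  n_hybrids = 100,
  environments = list(
    env_spec("2018", c(29, 36, 43, 51, 65, 79, 99), flowering_start_dap = 65,
             n_ranges = 20, n_rows = 10),
    env_spec("2019", seq(25, 116, by = 7), flowering_start_dap = 67,
             n_ranges = 20, n_rows = 10)),
  vi_names = c("VARI", "RCC", "GCC", "NGRDI"), seed = 42)
trial <- simulate_trial(cfg)
trial
#> Synthetic multi-environment trial
#>   hybrids: 100  markers: 1000  reps: 2
#>   environments: 2018 (7 flights), 2019 (14 flights)
#>   plot records: 400  VI records: 16800

blues <- rbind(fit_blues(trial$plots, "gy", "2018"),
               fit_blues(trial$plots, "gy", "2019"))
estimate_heritability(trial$plots, "gy", "2018")
#> [1] 0.6175142

blups <- rbind(fit_temporal_blups(trial$vi_obs, environment = "2018"),
               fit_temporal_blups(trial$vi_obs, environment = "2019"))
temporal_correlation(blups, blues, "VARI", "gy", "2018")
#> Temporal correlation VARI ~ gy in 2018: 0.290 +/- 0.015 (7 flights)

fl <- c("2018" = 65, "2019" = 67)
scores <- merge_environments(lapply(names(fl), function(ev)
  build_score_matrix(fit_fpca_env(blups, ev, window = "until_flowering",
                                  flowering_start_dap = fl[[ev]]))))
dim(scores)   # 100 hybrids x 2 environments, 4 VIs x 2 scores + keys
#> [1] 200  10

G  <- genomic_relationship(trial$markers)
P1 <- phenomic_relationship(scores)
records <- scores[, c("hybrid", "environment")]
ksets <- list(M1 = assemble_model("M1", records, G = G),
              M4 = assemble_model("M4", records, G = G, P1 = P1))
cvd  <- build_cv_data(blues, ksets)
plan <- make_folds(sort(unique(records$hybrid)), k = 5, repeats = 2, seed = 1)
res  <- run_within_env(cvd, c("M1", "M4"), plan,
                       gibbs_config(n_iter = 2000, burn_in = 500, seed = 1))
summarize_cv(res)
#>   model_id scenario     mean_r        sd_r n_cells
#> 1       M1      CV1 0.06561972 0.163531874      20
#> 3       M1      CV2 0.95683690 0.004839632      20
#> 2       M4      CV1 0.19229204 0.187555310      20
#> 4       M4      CV2 0.93202702 0.007078876      20
```

Reading the output: CV2 (tested hybrids, in-sample) is high for both
models; CV1 (untested hybrids) is where the models differ — adding the
early-season phenomic kernel (M4) raises the ability for unphenotyped
hybrids over the genomic-only model (M1), because untested hybrids
still have drone data. At this desk scale (100 hybrids, 1,000
independent markers) genomic CV1 ability is intrinsically modest; it
rises with training-set size and marker linkage.

A full preset-shaped run is available from the shell:

```sh
Rscript scripts/pipeline.R --preset pop1 --trait gy \
    --models M1,M4 --scenarios within,loeo --repeats 2 --seed 1 \
    --out results/pipeline
```

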