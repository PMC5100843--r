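# hybridpred

Genomic prediction of maize single-cross (hybrid) performance from
combining-ability mixed models, with a full synthetic-data generator for the
early stages of a two-heterotic-group (SSS/NSS) breeding pipeline.

## Who this is for

Quantitative geneticists and breeding-methods researchers who want a tested,
self-contained implementation of single-cross genomic prediction — parental
GCA/SCA models, covariance-among-hybrids projection, and the
T2/T1F/T1M/T0/novel-family cross-validation scenarios — that can be exercised
end-to-end without access to proprietary trial data.

## The model

Stage 1 fits the multi-environment trial model to plot data

    y_iklq = mu + g_i + e_k + (ge)_ik + r_l(k) + b_q(kl) + eps_iklq

with single-cross effects g ~ N(0, I sigma2_g) and environment / replicate
fixed, yielding single-cross BLUPs and the entry-mean heritability

    H2 = sigma2_g / (sigma2_g + sigma2_gxe / h_k + sigma2_e / h_t).

Stage 2 decomposes hybrid value into general and specific combining ability,

    y_ijklq = mu + f_i + m_j + s_ij + e_k + r_l(k) + b_q(kl)
              + (fe)_ik + (me)_jk + (se)_ijk + eps,

with f ~ MVN(0, G_f sigma2_GCA_F), m ~ MVN(0, G_m sigma2_GCA_M),
s ~ MVN(0, S sigma2_SCA), where G_f and G_m are simple marker-similarity
matrices of the female and male parents and S[(ij),(i'j')] =
G_f[i,i'] G_m[j,j'] is the dominance relationship among crosses. REML
estimation runs on Henderson's mixed-model equations with user-supplied
covariance matrices; parents without phenotypes ride along as zero-record
levels and receive kinship-propagated GCA BLUPs.

Untested hybrids are predicted four ways:

* **1a** — parent GCA: `mu + f_i + m_j`
* **1b** — GCA + SCA: `mu + f_i + m_j + s_ij`
* **2a** — additive covariance among crosses: `mu + C_ut C_tt^-1 (y_t - mu)`
  with C elements `G_f sigma2_F + G_m sigma2_M` (+ `sigma2_e / n` on tested
  diagonals)
* **2b** — as 2a plus the dominance term `G_f G_m sigma2_SCA`

plus the *modified* 2a/2b variants that replace both GCA variances by their
average, and an all-pairs factorial predictor over every female x male
combination. Prediction accuracy is the Pearson correlation between predicted
and observed (stage-1 BLUP) values divided by sqrt(H2), with bootstrap SEs
from 200 paired resamples.

## Worked example

```r
library(hybridpred)
cfg <- run_config(seed = 11, trait = "gy",
                  cv_scenarios = c("T2", "T0"), cv_methods = "1a",
                  cv_reps = 2, verbose = FALSE)
report <- run_pipeline(cfg)
print(report)
```

```
Pipeline run (seed 11 , trait gy )
 crosses: 312 | markers post-QC: 865
 H2 = 0.629 | SCA ratio = 0.31
  CV T2_1a      mean accuracy 0.783
  CV T0_1a      mean accuracy 0.586
```

The run simulates six founder inbreds, six biparental DH/RIL families with
the reference family sizes (8/36/2 and 35/69/67), a sparse factorial of 312
single crosses in nine single-cross families, and five environments x three
replicates of incomplete-block trials with ~6% lost plots. Marker QC retains
865 of 2296 simulated SNPs; the entry-mean heritability of the simulated
grain yield lands near the 0.58 target; and the T2 scenario (both parents
tested) is predicted substantially better than T0 (neither parent tested),
the central qualitative result of this design. The factorial report ranks all
7866 possible crosses:

```r
head(report$factorial$top[, c("female", "male", "prediction")], 5)
#>        female       male prediction
#>    SSS2_DH030 NSS1_DH020   9.404095
#>  SSS1r_RIL001 NSS1_DH020   9.335312
#>    SSS2_DH020 NSS1_DH020   9.315342
#>    SSS2_DH030 NSS1_DH010   9.279755
#>    SSS1_DH004 NSS1_DH020   9.272236
report$factorial$n_tested_in_top
#> [1] 11
```

Only 11 of the top-100 predicted crosses were among the 312 actually
"field-tested" — most of the best material was never made, which is the
argument for predicting the full factorial.

## Package layout

* `R/` — simulation (`simulate_population`, `build_cross_design`,
  `simulate_genetic_values`, `simulate_trials`), marker QC and kinship
  (`apply_marker_filters`, `additive_similarity`, `dominance_relationship`),
  the REML engine (`mixed_model_spec`, `fit_reml`, `restricted_loglik`,
  `prediction_error_variance`), trial analysis (`fit_trial_model`,
  `entry_mean_heritability`, `family_summaries`), combining ability
  (`fit_gca_sca`, `sca_ratio`, `gca_se_profile`), hybrid prediction
  (`predict_1a/1b`, `build_hybrid_covariances`, `predict_2`,
  `predict_factorial`) and evaluation (`run_loocv`,
  `run_leave_family_out`, `accuracy`, `bootstrap_se`).
* `vignettes/single-cross-prediction.Rmd` — the methods vignette: model
  assumptions, generator design, numerical choices, limitations.
* `tests/testthat/` — unit, property and acceptance-level tests.
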