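---
title: "Methods: genomic prediction of single crosses from combining-ability models"
author: "hybridpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic prediction of single crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of what it computes and why the
pieces are built the way they are: the two mixed models and their
assumptions, the prediction methods, the cross-validation protocol, what the
synthetic-data generator does and does not emulate, and the numerical
choices that a maintainer would otherwise have to reverse-engineer from the
code.

## The problem

Early in a hybrid maize program, inbred progenies (mostly doubled haploids,
some recombinant inbred lines) are extracted from a handful of biparental
families on each side of a heterotic pattern — here a female pool (Stiff
Stalk type) and a male pool (non-Stiff Stalk type). Only a sparse subset of
the possible female x male single crosses can ever be field-tested. The
question the package addresses is how well the untested crosses can be
predicted from genomic relationships among the parents plus multi-environment
trial data on the tested crosses, and how that accuracy depends on whether a
cross's parents were themselves represented in the training data.

## Stage 1: trial analysis

`fit_trial_model()` fits, to plot-level data,

y = mu + g + e_k + (ge) + r_l(k) + b_q(kl) + eps,

with environment and replicate-within-environment fixed and the single-cross
effect g (identity covariance), the cross-by-environment interaction, and the
incomplete-block effect random. Unbalancedness from lost plots is handled by
the likelihood. Its products are (a) single-cross BLUPs (`hybrid_blups()`),
reported as mu + g so they live on the trait scale — correlation-based
accuracy is unaffected by this centering choice; and (b) the entry-mean
heritability

H2 = sigma2_g / (sigma2_g + sigma2_gxe / h_k + sigma2_e / h_t),

where h_k is the harmonic mean of per-cross observation counts within an
environment and h_t the harmonic mean of total counts per cross. The h_k
divisor is implemented exactly as that definition reads; a plausible
alternative reading divides the interaction variance by the number of
environments instead, and is exposed as `gxe_divisor = "n_env"` without
changing the default. `family_summaries()` refits the same model per
single-cross family.

## Stage 2: combining ability

`fit_gca_sca()` decomposes hybrid value into female GCA f, male GCA m and
cross-specific SCA s with covariances G_f sigma2_GCA_F, G_m sigma2_GCA_M and
S sigma2_SCA. The additive matrices are simple marker-similarity
coefficients: G[i,j] = mean over markers of 1 - |x_i - x_j| / 2, which is 1
for identical inbreds and 0 for opposite homozygotes — chosen as the
standard simple-matching coefficient for fully homozygous material, since
"similarity" admits several formulas and the package needed one fixed
definition. The dominance matrix multiplies the parental similarities
elementwise, S[(ij),(i'j')] = G_f[i,i'] G_m[j,j'], the classical dominance
covariance for hybrids between unrelated pools. Parents present in G_f or
G_m but absent from the data enter the mixed-model equations as zero-record
levels, so their GCA BLUPs are pure kinship propagation — this is exactly
equivalent to regressing on the covariance with tested relatives, but falls
out of one linear solve.

Environment interactions (fe), (me), (se) are modeled with Kronecker
covariances (relationship matrix x identity over environments) — the
simplest structure consistent with independent environments — and are
included by default. `reduced = TRUE` drops them; for designs of a few
hundred crosses they are weakly identified and dominate the fitting cost, so
the pipeline, the tests and the cross-validation default use the reduced
configuration.

## The REML engine

No installed mixed-model package accepts arbitrary user covariance matrices
over random-effect levels, so the engine is written here, against
Henderson's mixed-model equations (MME). The restricted log-likelihood is
evaluated through the MME identity

-2 l_R = log|R| + log|G| + log|C| + y'Py,

never forming an n x n matrix; the residual variance is profiled out
analytically and a bounded quasi-Newton search (L-BFGS-B) runs on the log
variance ratios theta_c / sigma2_e. The contract is objective-level: the
optimizer is interchangeable as long as the optimum matches a generic
bounded maximization of `restricted_loglik()` — that equivalence, plus
dense-algebra checks of the likelihood values, BLUPs and prediction-error
variances (PEVs), is asserted in the test suite rather than assumed.

Numerical choices:

* Variance ratios are bounded in [1e-8, 1e8]; a component at the lower bound
  is reported with a boundary flag, not an error. The relative-change
  convergence tolerance is 1e-8.
* Covariance matrices are inverted by Cholesky with jitter escalation
  (0, 1e-8, 1e-6, 1e-4 times the mean diagonal); the jitter used is logged.
  A matrix that still fails is reported as singular rather than silently
  regularized further.
* PEVs are diagonal elements of the inverse MME coefficient matrix, computed
  per requested level by triangular solves, so a full inverse is never
  stored. SE(BLUP) = sqrt(PEV); a level with no records and identity
  covariance recovers its prior variance exactly.
* Likelihood-ratio tests of a component use the 0.5:0.5 mixture of
  chi-square(0) and chi-square(1), the standard boundary correction.
* Per-record weights implement heteroscedastic residuals of the form
  sigma2_e / w. Fully heterogeneous per-environment residual and block
  variances are not fitted; this affects the weighting of observations, not
  the definition of any prediction method, and is the package's documented
  simplification.

## Prediction methods

With a fitted model, method **1a** predicts mu + f + m, and **1b** adds the
SCA BLUP, where the SCA of a never-observed cross is its conditional prior
mean given the observed crosses' BLUPs, S_uo S_oo^-1 s_o, with rows of the
all-pairs S built on demand in chunks (the full 7866 x 7866 matrix is never
materialized).

Methods **2a/2b** instead project the stage-1 BLUPs of tested crosses
through covariance matrices assembled from the variance components:
off-diagonals G_f sigma2_F + G_m sigma2_M (2b adds G_f G_m sigma2_SCA), and
tested-cross diagonals additionally carry sigma2_Xbar = sigma2_e / n, the
error variance of that cross's mean. The projection centers y_t by the grand
mean and re-shifts afterwards; with no intercept column inside the
projection this is exactly equivalent to projecting raw values when means
are homogeneous, and avoids leaking a nonzero mean through the shrinkage
when they are not. `center = FALSE` restores the raw projection. The
*modified* variants replace both GCA variances by their average in every
additive term — the diagnostic the package implements for asking whether
separate female/male variances help or hurt when one pool is more variable
than the other.

When the components are held fixed, the BLUP of any linear combination of
random effects equals its covariance projection onto the data — the tests
assert this identity on dense toy problems. The cross-validation driver
exploits it: per fold, methods 1a/1b are computed as projections of the
entry-mean response under the full model covariance (including SCA), and
methods 2a/2b as the covariance projections defined above, so each fold is
one Cholesky solve of the training covariance instead of a REML refit.
Methods 1 and 2 remain genuinely different procedures in the driver: they
use different response vectors (weighted entry means vs stage-1 BLUPs) and
different covariance structures.

## Cross-validation protocol

Four leave-one-individual-out scenarios differ in what the training pool may
contain relative to the validation cross: T2 excludes only the cross itself;
T1F additionally excludes every cross sharing its male parent (so only the
female remains tested); T1M excludes the female-sharing crosses; T0 excludes
both. Pool construction is audited at run time: an assertion fails if any
pool contains the validation cross or an excluded parent. For each of the
repetitions (default 30) and each hybrid, a training set of fixed size
(default 250) is drawn without replacement from the pool; the integrated
prediction vector is correlated with the stage-1 BLUPs and divided by
sqrt(H2). With 312 crosses and 30 repetitions the driver draws 9360 training
sets, and the count is recorded on the result object. Bootstrap SEs resample
the (predicted, observed) pairs 200 times per repetition; the SD of the
resampled correlations is averaged over repetitions. Leave-one-family-out
validation holds out each single-cross family in turn and reports accuracy
per family, by default only for families with at least 25 crosses, since
correlations over fewer pairs are too unstable to interpret.

Two defaults deserve justification. First, variance components are estimated
once (on the full data, or supplied) and reused across folds; re-estimating
them for each of the 9360 training samples at plot level is out of
computational reach, and at fixed components the fold predictions are exact
BLUPs. A `refit = TRUE` path re-estimates components per training sample at
the entry-mean level for small designs. Second, the whole-population H2
scales scenario accuracies; family-level reporting can use family-specific
H2 via `family_summaries()`, and both conventions are stated wherever
results are printed. Seeding is hierarchical — repetition r, hybrid v uses a
stream keyed by (r, v) — so scenario runs are comparable across methods and
any fold is reproducible in isolation.

## The synthetic-data generator

The generator exists so that every downstream stage is testable without
external data, and its defaults are the conditions of the emulated breeding program:

* **Founders and families.** Three fully homozygous founders per pool, the
  three possible biparental crosses within each pool, family sizes (8, 36,
  2) and (35, 69, 67). DH progenies are doubled gametes of the family F1:
  crossovers per chromosome Poisson with mean map-length/100, uniform
  breakpoints, no interference (Haldane). RILs (about 10% of progenies) are
  approximated as fully homozygous lines generated by the same mechanism on
  a two-fold expanded map — the expected map expansion of a selfing series —
  because the analysis never distinguishes the two line types.
* **Genome.** Default 10 chromosomes of 150 cM carrying 2296 markers placed
  uniformly at random. Marker density and placement are plumbing, not
  biology: no attempt is made to match real maize linkage disequilibrium.
* **Divergence.** Between-pool allele-frequency divergence defaults to 0.3:
  at the simulated founder sample sizes this retains roughly 40% of raw
  markers through the polymorphic-in-both-pools filter (the 2296 default is
  a post-filter count) while keeping within-pool polymorphism
  realistic. Divergence 0 makes the pools exchangeable; 1 fixes opposite
  alleles.
* **Cross design.** Per-cell cross counts of the nine single-cross families
  follow the fixed reference table (27, 39, 33, 51, 49, 49, 21, 19, 24; 312 total);
  parent pairs are sampled uniformly at random within cells without
  duplicates; only approximate balance is assumed, so crosses are random and
  approximately balanced.
* **Genetic values.** The default draws f, m, s from their model
  distributions at the grain-yield preset components (0.22, 0.20, 0.05);
  plant-height and staygreen presets carry (28.66, 34.48, 2.6) and (0.12,
  0.23, 0.01). A QTL mode assigns additive and dominance effects to marker
  loci and decomposes realized hybrid values into GCA/SCA by marginal means,
  for tests that need genotype-driven truth.
* **Trials.** Five environments x three replicates, fixed equally spaced
  environment effects, incomplete blocks of 26 consecutive plots within each
  randomized replicate, independent per-(cross, environment) interaction
  draws with a single variance, i.i.d. plot dropout at 6% standing in for
  stand-count discards and seed shortages. Structured (fe)/(me)/(se)
  generation is available as an option.
* **Noise calibration.** Because similarity-based kinships correlate the
  parent effects, the realized variance among the 312 crosses is smaller
  than the marginal component sum. The pipeline therefore rescales the
  preset noise variances by var(realized g) / 0.47 so that the entry-mean
  heritability of the simulated trait stays at the trait's whole-population
  value (0.58 grain yield, 0.89 plant height, 0.81 staygreen) under the
  default field design. The effect magnitudes themselves are never rescaled.

What passing tests on this generator do *not* show about real data: the
simulated markers are in linkage equilibrium within founder pools, residuals
are homoscedastic across environments, dropout is independent of genotype,
and the founder pools are symmetric in diversity. Accuracies on synthetic
data are therefore expected to sit somewhat above field results at the same
nominal heritability, and the package's claims are about orderings and
recoveries, not absolute accuracy levels.

## Problem sizes used in the checks

The automated checks run the full 312-cross design for everything that is
design arithmetic (cross totals, the 7866-pair factorial, the 9360
training-set draws), a 50-dataset recovery study at the grain-yield
components on study-scale kinships, and 10-seed cross-validation contrasts
at 5 repetitions per scenario; oracle equivalences use instances of a few
dozen records where dense algebra is exact. These sizes were chosen as the
smallest at which each property is statistically decidable, and the methods
vignette is the single place they are recorded.

## Known limitations

* Heterogeneous per-environment error/block variances are not fitted
  (weighting simplification; see above).
* The REML engine is dense in the MME dimension; designs beyond a few
  thousand random-effect levels per fit are out of its intended range.
* Epistatic hybrid components, marker-effect (ridge) parameterizations, and
  training-set optimization are out of scope.
* The leave-one-family-out protocol reports correlations within families;
  with fewer than ~25 crosses these are noisy, and the package refuses to
  report them by default rather than printing unstable numbers.
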