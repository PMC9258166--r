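---
title: "Discriminant latent-variable models and age-dependent pathway analysis for two-group metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminant latent-variable models and age-dependent pathway analysis for two-group metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oplsage)
```

## The analysis in one paragraph

`oplsage` implements a complete analysis for case/control targeted-metabolomics
cohorts of the kind produced by commercial quantitative panels (hundreds of
named metabolites, tens of subjects per group): discriminate the groups with
latent-variable models (PLS-DA and OPLS), validate the models by permutation
and bootstrap resampling, select a robust metabolite panel by a four-step
VIP/PCA procedure, classify the principal components of the selected panel by
the group in which they correlate with age, and map each component's
metabolites onto pathways by over-representation analysis. The motivating use
case is Parkinson's disease versus healthy controls, where the scientific
question is which perturbed metabolic pathways track age in patients, in
controls, or in neither group. Because cohort data of this kind are rarely
deposited publicly, the package ships a synthetic-cohort generator with
planted, fully known structure; every stage is tested against that ground
truth.

## Models

### Autoscaling

Every matrix entering a latent-variable model is autoscaled: each metabolite
column is reduced to zero mean and unit variance, using the sample standard
deviation (denominator *n* - 1, the chemometrics convention; the choice is
stated explicitly so that tests are unambiguous). Inside every
cross-validation fold and every resampling round the scaling is refit on the
training part and applied to the held-out part. Scaling once up front would
leak held-out information into the predictability estimate Q2 and bias it
optimistically; the leakage-free behavior is the default and a
`rescale_in_resampling = FALSE` switch restores single up-front scaling.

### PLS-DA

Groups are encoded as a response `y` with cases +1 and controls -1.
Single-response partial least squares extracts components sequentially; with
one response the NIPALS inner loop converges in a single pass, so each
component has the closed form

* weight `w = X'y / |X'y|`,
* score `t = X w`,
* x-loading `p = X't / (t't)`,
* y-loading `q = y't / (t't)`,

after which `X` is deflated by `t p'`. The response is not deflated (the
standard single-response simplification; predictions are identical, textbooks
differ on this point). Regression coefficients are assembled as
`b = W (P'W)^-1 q`, so that `yhat = X b + ybar`, and the goodness of fit is
`R2Y = 1 - |y - yhat|^2 / |y - ybar|^2`. Each component is sign-fixed so that
its largest-magnitude x-loading is positive; this makes scores and loadings
deterministic across runs and platforms.

### OPLS

OPLS separates predictor variation into a label-predictive part and
orthogonal components that are uncorrelated with the class label. Each
orthogonal round computes the PLS weight and loading as above, takes the part
of the loading orthogonal to the weight,
`w_o = p - (w'p) w`, normalizes it, and deflates `X` by the resulting
orthogonal component `t_o p_o'`. By construction `t_o' y = 0` exactly, which
the tests assert at `1e-8` relative tolerance. The predictive PLS model is
then fitted on the filtered matrix; prediction of new samples applies the
stored orthogonal filtering before the predictive regression. If the
orthogonal weight norm falls below `1e-10` the loop stops early and the
realized number of orthogonal components is recorded. With zero orthogonal
components OPLS reduces exactly to PLS-DA.

The default model comparison mirrors the motivating study: a 3-component
PLS-DA against an OPLS model with 1 predictive and 3 orthogonal components.

### Predictability

`Q2 = 1 - PRESS/SS` is estimated by stratified K-fold cross-validation
(default `k_folds = 7`, a common chemometrics choice; the source study does
not state its K), with per-fold refit of both the scaling and the model.
`PRESS` sums squared errors of held-out predictions and `SS` is the total
response sum of squares about the global mean.

### VIP

Variable influence on projection summarizes each metabolite's contribution to
the predictive components:
`VIP_j = sqrt( p * sum_a SSY_a w_ja^2 / sum_a SSY_a )`, with `SSY_a` the
response variance explained by component `a`. The mean squared VIP is exactly
1, which the tests assert as an algebraic identity. For OPLS only predictive
components enter: the VIP used here measures discrimination importance, which
is what the downstream selection needs. (Variants that include the
orthogonal share exist; the source study does not specify its variant.)
A consequence worth noting: with a single predictive component, orthogonal
deflation leaves `X'y` unchanged, so the VIP ordering of an OPLS model equals
that of the corresponding one-component PLS - the OPLS machinery matters for
prediction and for the overfitting diagnostic, not for the VIP screen itself.

## Model validation

### Permutation test for R2Y and Q2

Labels are randomly permuted (default 1000 times), the model refitted, and
R2Y and Q2 recorded. One-sided empirical P-values use the +1 correction
`(1 + #{perm >= observed}) / (1 + n_perm)` and therefore lie in (0, 1]. Two
details keep this test exactly calibrated:

* The cross-validation folds inside the test are drawn *without looking at
  the labels*, and the same folds score the observed and every permuted
  label vector. Stratifying the folds on the observed labels would treat the
  observed labels more favorably than the permuted ones and measurably
  shifts the null (we observed mean null P of 0.45 instead of 0.50 with
  stratified folds at n = 20).
* Exchangeability of the permutations is never mixed with the diagnostic
  sweep described next.

### Overfitting diagnostic

A model that fits permuted labels as well as the real ones is overfitted.
The diagnostic declares `"overfit"` when the fraction of permutations whose
R2Y reaches the observed R2Y exceeds 0.05, or when permuted R2Y fails to
increase with label similarity. For the similarity trend, uniformly random
permutations are useless at these sample sizes - the correlation between a
random permutation and the original +/-1 labels concentrates within about
+/-0.25 - so the report additionally records a sweep of *partial*
permutations (swapping k case/control label pairs, k = 1 .. n/2) whose
similarity spans the whole axis, as in the classical permutation-validation
plot. The trend is computed against absolute similarity because the fit is
invariant to a global sign flip of the labels. Partial permutations are not
exchangeable draws and never enter any P-value.

### Bootstrap model validation

Subjects are resampled with replacement, stratified by group (default 500
replicates), and the cross-validated Q2 of each replicate is recorded.
Duplicated subjects must never sit on both sides of a validation split, so
folds are assigned over the unique subjects of a replicate and duplicates
inherit their subject's fold. The reported model P-value is the share of the
permutation-null Q2 distribution at or above the observed Q2, which is
exactly calibrated under the null; the bootstrap distribution and its
percentile interval quantify the stability of Q2 under subject resampling.
We deliberately do not threshold the null at the bootstrap median: resample
cross-validation is biased low (fewer unique subjects per replicate), and on
200 null datasets that construction produced a Kolmogorov-Smirnov distance
of 0.145 from uniformity (P = 4e-4) - it double-counts resampling pessimism.

### Loading permutation test and ROC

Per-metabolite two-tailed loading permutation tests compare each
metabolite's predictive loading against its permutation null. The ROC AUC is
computed by the rank (Mann-Whitney) identity with ties counted one half, and
its 95% confidence interval by a stratified percentile bootstrap over
subjects.

## The four-step metabolite selection

1. **Training-split screen.** A single stratified split assigns 80% of each
   group to training. The OPLS model is fitted on the training part and
   metabolites pass if `VIP > 1`, the loading permutation P is below 0.05
   and the absolute loading exceeds 0.04. The model is refitted on the
   selected columns and all subjects scored for a bootstrap ROC/AUC. The
   split is drawn once, seeded, and logged.
2. **Stability filter.** Model training is repeated (default 1000 rounds) on
   resamples of 80% of each group drawn *with replacement* (the m-out-of-n
   bootstrap reading of "resampling with replacement of 80%"; a switch
   selects subsampling without replacement instead). A metabolite is
   retained when its VIP exceeds 1 in strictly more than 95% of rounds; a
   fraction of exactly 0.95 is dropped, reading "more than 95%" literally.
3. **PCA reduction.** PCA (singular value decomposition) of the autoscaled
   submatrix of retained metabolites, over all subjects. `N_pca` is the
   smallest number of components reaching 80% cumulative variance. Within
   each component, metabolites with `|c_j| > 0.9 max |c|` are significant;
   coefficients are the unit-norm loadings, sign-fixed so each component's
   largest coefficient is positive. The 0.9-max rule is applied within each
   component (the natural reading of "the most important contribution to
   each component").
4. **Intersection.** The final panel is the intersection of the stability
   set with the union of the per-component significant sets; each metabolite
   is assigned to the component with its largest significant coefficient.

The selection trail (VIP, loading, loading P, stability fraction, component,
coefficient, final flag for every metabolite) is written as a single table.

## Age dependence and pathways

Component scores are correlated with age by Spearman rank correlation,
separately within cases and controls, using mid-ranks for ties and the
t-approximation for P-values (adequate at n around 39 per group; exact
enumeration is impractical there and the approximation is oracle-tested
against the reference implementation). A group counts as age-correlated when
`|r| > 0.5` and `P < alpha / N_pca` (Bonferroni over components); each
component is then classified `case-only`, `control-only`, `both` or
`neither`. The classification records *which group* correlates, not the
sign: a disease-only-in-patients pathway may decline with age in patients
while a healthy-aging pathway rises in controls.

A confirmatory metabolite-level check verifies that each selected
metabolite's own within-group correlations repeat the classification of its
component, at unadjusted alpha (the step is confirmatory, not a screen;
Bonferroni over the final panel at these group sizes would have negligible
power) and with the sign consistent with
`sign(coefficient) * sign(component r)`.

Over-representation analysis tests each pathway (intersected with the
measured universe: all metabolites after exclusions, the standard ORA
convention) both by the exact hypergeometric upper tail and by an empirical
permutation null of random same-size queries; the two agree as the
permutation count grows, which is tested. Per component, the enrichment of
the component's final metabolites yields the headline table "pathway by age
behavior".

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes:

* 39 cases aged 71 +/- 6.4 years and 39 controls aged 73 +/- 7.1 years;
* 628 metabolites (a 630-analyte panel minus two therapy-confounded
  analytes, which the preprocessing drops by name);
* three planted metabolite blocks, each driven by one latent factor:
  a block whose factor correlates with age *only in cases* (target Spearman
  r = -0.52), one correlating *only in controls* (target +0.64), and a
  disease-only block with no age structure;
* unplanted metabolites are independent log-normal noise.

Block log-concentrations are
`baseline + case shift + loading * factor + residual noise`; concentrations
are exponentiated, so all values are strictly positive.

Several design choices deserve explanation because they were forced by the
mathematics of the downstream procedure, and they state what passing tests
do and do not show about real data:

* **Age coupling is exact in-sample and targets Spearman.** The factor is
  `w z(age) + sqrt(1 - w^2) eta` within each group, with `eta` standardized
  and orthogonalized against standardized age, and `w` found by bisection so
  that the factor's realized in-sample Spearman correlation equals the
  target. The screen's retention rule is `|r| > 0.5` and the headline target
  is 0.52: with loose coupling the classification of the case-age component
  would be a coin flip by construction, telling us nothing about the code.
  With exact factor-level coupling, the only attenuation left is the
  component-score noise, and correct classification becomes the majority
  outcome - which is what the acceptance suite asserts, over 50 seeds.
* **Blocks are heterogeneous** (sizes 16/8/6, within-block correlations
  0.96/0.92/0.88). Equal blocks have degenerate population eigenvalues, and
  sample principal components then mix the blocks arbitrarily - a real
  phenomenon, but one that would make the component-to-block mapping
  meaningless in the very fixture meant to test it. Real metabolite
  families (sphingomyelins, ceramides, fatty acids) differ in size and
  tightness in just this way.
* **Planted case/control shifts alternate in sign within each block**
  (log2 ratio magnitudes 0.45/0.55/0.6, i.e. concentration ratios about
  0.66-1.52, in the upper range reported for targeted panels). A
  uniform-sign shift across a block is collinear with the block's factor
  direction and couples all blocks through a shared rank-one disease
  contrast, which rotates the principal components away from the blocks.
  Sign-mixed shifts spread the disease contrast over within-block contrasts;
  mixed directions within a biochemical family are indeed seen in published
  panels. The shared contrast then surfaces as its own age-independent
  component, which is exactly where the disease-only block lands.
* **Effect magnitudes were calibrated once** so that generated cohorts
  reproduce the order of magnitude of the separation statistics reported
  for real cohorts of this design (cross-validated OPLS Q2 around 0.5-0.8,
  step-1 AUC near 1 with a confidence interval lower bound above 0.9, about
  30 stability-validated metabolites), and were not revisited afterwards.

What the generator does *not* emulate: batch effects and instrument drift,
censoring at the limit of detection (the half-minimum imputation policy at
the I/O layer is exercised by dedicated fixtures instead), non-normal
concentration distributions beyond log-normality, and correlated null
metabolites. Passing the planted-recovery suite therefore shows that the
procedure recovers structure *of the planted kind at the planted strength*;
it does not certify performance on data whose nuisance structure differs.

## Numerical choices and degenerate inputs

* NIPALS tolerance `1e-12`; orthogonal weight floor `1e-10`; requesting more
  components than the rank supports truncates with a warning.
* Constant metabolite columns are dropped with a warning by `autoscale()`;
  inside resampling loops scale floors keep matrix dimensions fixed.
* Stratified folds are redrawn (with warning) if a training fold would be
  single-class; leave-one-out is detected and handled exactly.
* Empirical P-values all use the +1 correction and lie in (0, 1].
* Ties at selection thresholds (VIP exactly 1, stability exactly 0.95) are
  dropped - strict inequalities throughout, following the "more than"
  wording of the procedure.
* All randomness flows from one master seed through named substreams
  (`stage_seed`), so adding a stage never shifts another stage's draws and
  identical configurations reproduce byte-identical result tables.

## Problem sizes used by the test suite

The packaged tests run the full pipeline at the cohort's native size
(78 x 628) with reduced resampling depths (150 permutations, 250 stability
rounds, 100 bootstrap replicates) over 50 seeds for the recovery suite, and
use 200 null datasets of size 20 x 8 for the calibration suite; these sizes
were chosen as the smallest at which the asserted properties are stable
Monte-Carlo statements. The acceptance script runs one cohort at the full
default depths (1000 permutations, 1000 stability rounds, 500 bootstrap
replicates).

## Known limitations

* Single-response models only: no multi-class discrimination, no O2PLS, no
  kernel or sparse variants.
* The bootstrap "model P-value" construction in the literature this package
  follows is not fully specified there; our construction is documented
  above and chosen for exact null calibration.
* The age screen classifies components, not individual metabolites; a
  metabolite's own age correlation enters only the confirmatory consistency
  check.
* Pathway analysis is plain over-representation against user-supplied sets;
  no pathway-topology impact scores and no identifier translation.

## A worked example

```{r example, eval = FALSE}
library(oplsage)

sim <- generate_dataset(simulation_design(seed = 5))
config <- run_config(seed = 5, n_permutations = 200,
                     n_bootstrap_model = 100, n_bootstrap_vip = 300)
report <- run_pipeline(config, sim$dataset,
                       truth_pathway_sets(sim$truth, seed = 5),
                       out_dir = "results")
print(report)
```

The printed report summarizes the fitted models (R2Y/Q2), the validation
verdicts, the selection funnel, each component's age classification and the
top pathway per component; the delimited tables and a JSON run manifest are
written under `results/`.
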