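---
title: "Latent class mixed models for heterogeneous cognitive decline: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent class mixed models for heterogeneous cognitive decline: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Cognitively unimpaired older adults with biomarker evidence of Alzheimer
pathology decline at very different rates: most remain stable over the
span of a prevention trial, a minority decline slowly, and a small group
declines rapidly. A single mixed model with one mean trend hides this
structure. `cogmix` models it directly with a latent class mixed-effects
model (LCMM) of a longitudinal cognitive composite (PACC; higher is
better), and carries the classes through the downstream questions that
matter for trial design: can the classes be predicted from baseline data
alone, which baseline variables characterize them, and how much power does
a trial have in each class?

## The model

The LCMM couples two submodels. For subject $i$ in latent class
$g \in \{1,\dots,G\}$, the **longitudinal submodel** for the Box-Cox
transformed outcome at visit $j$ is

$$ y_{ij} \mid (c_i = g) \;=\; \alpha_{g0} + \sum_{l=1}^{d} \alpha_{gl}
   B_l(t_{ij}) + w_{ij}^\top \gamma + b_i + \varepsilon_{ij}, $$

with $B_l$ a natural cubic spline basis in years since each subject's
first visit, $b_i \sim N(0, \sigma_b^2)$ a subject random intercept, and
$\varepsilon_{ij} \sim N(0, \sigma_e^2)$. Spline coefficients
$\alpha_g$ are class-specific; covariate effects $\gamma$ (treatment
assignment, plasma P-tau217, amyloid PET SUVr, APOE $\varepsilon$4, sex,
age, education, hippocampal atrophy z-score, test stimulus version) are
shared across classes. The **membership submodel** is a multinomial logit
on the same baseline covariates minus the stimulus version,

$$ \Pr(c_i = g \mid x_i) = \pi_{ig} =
   \frac{\exp(\zeta_g^\top x_i)}{\sum_h \exp(\zeta_h^\top x_i)},
   \qquad \zeta_1 = 0. $$

Integrating the random intercept analytically, each subject contributes a
finite mixture of multivariate normal densities
$L_i = \sum_g \pi_{ig}\,\phi(y_i;\, S_i\alpha_g + W_i\gamma,\,
\sigma_b^2 J + \sigma_e^2 I)$.

### Estimation

Estimation is maximum likelihood by EM, treating class membership as
missing data. The M-step separates into three exact or monotone pieces:

* $\zeta$: a convex weighted multinomial-logit problem with the posterior
  matrix as fractional targets, solved by Newton-Raphson warm-started from
  the current coefficients, with step halving so the objective never
  decreases;
* $(\alpha_1,\dots,\alpha_G,\gamma)$: a joint $\tau$-weighted generalized
  least squares solve. Subjects are grouped by visit-time pattern so the
  normal equations accumulate over a handful of small dense blocks rather
  than per subject;
* $(\sigma_b,\sigma_e)$: for the random-intercept structure, the
  closed-form EM update that treats the intercepts as additional missing
  data (one such step cannot decrease the expected log-likelihood at
  fixed posteriors and means); for intercept+slope, safeguarded
  Nelder-Mead on the log-Cholesky scale.

Because every step is a (generalized) EM step, the observed
log-likelihood is non-decreasing across iterations; the test suite
asserts this on every fit it runs, which turns a textbook property into a
continuous regression check on the whole estimation path. Convergence is
declared at $|\Delta \ell| < 10^{-6}$ (or a parameter change below
$10^{-4}$), with a 500-iteration cap.

Mixture likelihoods are multimodal, so `fit_lcmm()` is multi-start: a
base start from k-means on each subject's (baseline outcome, crude slope)
pair plus jittered perturbations, keeping the best likelihood (default 10
starts; the simulation batteries use 2-3 because the synthetic classes
are well separated at the optimum).

### Label switching and canonical order

Classes are reordered after fitting by the model-implied mean outcome at
the maximum follow-up time, descending: class 1 is "stable", the last
class the fastest decliner. The membership submodel is re-expressed with
class 1 as reference so its coefficients read as log-odds of declining
versus stable. Cross-validation refits are additionally aligned to the
full-data model by minimal summed squared distance between class mean
curves on a 13-point grid, which resolves fold-level label switching
deterministically.

### Model choice

`select_model()` fits all combinations of spline degrees of freedom
(1-3) and class counts (1-3) and selects the minimum BIC,
$\mathrm{BIC} = -2\ell + p\log N$ with $N$ the number of subjects. ICL is
reported alongside as $\mathrm{BIC} + 2\sum_{ig} -\tau_{ig}\log\tau_{ig}$
(the entropy-penalized variant, so ICL $\ge$ BIC always). Near-ties
($\Delta\mathrm{BIC} < 2$) break toward fewer parameters; that rule is
arbitrary but deterministic, which matters more here.

### Uncertainty

Class trajectory bands come from the delta method on the
observed-information covariance of $(\alpha, \gamma)$, computed by
central-difference numerical differentiation of the log-likelihood at the
optimum (step $10^{-5}$ times parameter scale), holding $\zeta$ and the
variances at their estimates. Means and interval endpoints are
back-transformed through the inverse Box-Cox; the transform is monotone,
so endpoints map to endpoints. A test compares these bands against a
500-draw parametric-sampling interval and against the $1/\sqrt{N}$
scaling law.

## Preprocessing choices

* **Box-Cox**: $\lambda$ maximizes the standard profile likelihood
  (including the Jacobian term) by golden-section search on $[-3, 3]$ to
  $10^{-5}$. The composite can be negative, so a shift of $1 - \min(y)$
  is applied first and stored; the fitted transform is serialized and
  reused verbatim on held-out data. $\lambda$ is fitted on the pooled
  outcomes across all visits because the transform precedes class
  discovery in the pipeline.
* **Splines**: boundary knots at the minimum and maximum pooled
  observation time; interior knots at the median (df = 2) or tertiles
  (df = 3) of pooled observation times. Evaluation at new times
  extrapolates linearly beyond the boundaries (the natural constraint).
* **Hippocampal atrophy**: volume is residualized on intracranial volume
  by OLS, z-scored, and sign-flipped so higher = more atrophy; odds
  ratios for declining-class membership then come out above 1 for more
  atrophic brains, the direction in which results are usually read.
* **Tau PET composite**: arithmetic mean SUVr over eight cortical
  regions; subjects missing any region are excluded from tau models.
* **Covariate scaling**: continuous covariates are standardized
  internally (effects are per SD); binary covariates stay 0/1. A test
  verifies that standardized and raw fits are exact reparameterizations
  of each other.

## The synthetic cohort generator

Real participant-level data from the A4/LEARN studies are not shipped;
the generator exists so that every downstream stage is exercised against
known ground truth. `preset_a4learn_like()` encodes the study conditions:

* three classes mixing at 77/16/7 percent;
* class mean PACC trajectories anchored at the published values (stable:
  0.52 at baseline to 1.16 at 6 years; slow decliner: $-0.13$ to
  $-4.74$; fast decliner: $-0.98$ to $-15.8$). The published summaries
  report only baseline and 6-year means, so the interior (3-year) anchor
  is an interpolation choice: mildly accelerating decline for the
  decliner classes and an early practice-effect gain for the stable
  class. The curves are natural splines (df = 2, interior knot at 2.5
  years, boundaries 0 and 7);
* class-conditional covariate profiles taken from the published
  class-wise baseline table (e.g. P-tau217 mean (SD) 0.20 (0.09) / 0.33
  (0.16) / 0.45 (0.26) U/mL), Gaussian truncated at physiologic bounds;
* $\sigma_b = 2.0$, $\sigma_e = 1.25$, chosen so the within-class
  baseline SD ($\approx 2.36$) matches the published stable-class PACC
  SD; semiannual visits to year 3 then annual to year 7; per-interval
  monotone dropout hazards (0.045/0.06/0.08 by class) giving a median
  follow-up between 6 and 7 years; class-specific CDR progression
  probabilities (0.228/0.719/0.882).

The membership mechanism is *re-derived* rather than assumed: a
multinomial logit is fitted once, deterministically, to a large internal
draw from the class-conditional covariate mixture, and that logit becomes
the generative membership model. Simulated cohorts therefore satisfy the
estimator's membership assumption exactly, which is what makes the
parameter-recovery batteries meaningful. The preset's outcome transform
is the identity member of the Box-Cox family ($\lambda = 1$, shift 1), so
the anchors are exact on both the model and observed scales; recovery
tests pass this transform to the fitting pipeline, because refitting a
Box-Cox on mixture data estimates a different monotone scale on which the
generating spline coefficients are not comparable.

What the generator does *not* emulate: treatment effects, site and
scanner effects, non-Gaussian residuals, outcome-dependent dropout
(dropout is missing-at-random within class, the mechanism under which
the LCMM likelihood is valid), and visit-window jitter. Passing tests
therefore demonstrate correctness of the machinery under the model's own
assumptions, not robustness to their violation.

## Cross-validated baseline-only prediction

Ten folds stratified by latent class and P-tau217 tertile (tertiles over
the full sample: a stratification variable, not a fitted quantity). Each
fold refits the LCMM on the training 90% — including the Box-Cox
transform, the spline knots, and the covariate scaling, so no held-out
information leaks through preprocessing — and predicts held-out subjects
from baseline data only: the membership prior combined with the Gaussian
density of the single baseline outcome (one visit at $t = 0$, marginal
variance $\sigma_b^2 + \sigma_e^2$). "Baseline data" is interpreted as
covariates *plus* the baseline outcome, because the baseline composite is
itself informative; a `use_outcome = FALSE` flag gives the prior-only
ablation. A permutation test asserts the no-leakage contract: shuffling
held-out post-baseline outcomes leaves predictions bit-identical.

Discrimination is summarized with precision-recall curves, using the
average-precision estimator (step interpolation) rather than trapezoidal
interpolation, which is optimistic in PR space. Accuracy intervals are
Wilson. The hippocampal atrophy z-score is computed once on the full
cohort before fold assignment: it uses only baseline covariates, and
refitting a two-parameter OLS inside each fold would change nothing
material while complicating the transform plumbing.

## Trial power

Power for a class-specific trial uses two-sample t-test calculations on
completers: $n_{\mathrm{eff}} = n(1 - \mathrm{attrition})$ per arm, with
the treatment effect anchored as a fraction of the "maximum possible
benefit" — the difference between the amyloid-negative stable group's
mean and the target group's mean at the horizon. The default is the
normal approximation with both rejection tails (so power $\to \alpha$ as
the effect vanishes); an exact noncentral-t mode
(`stats::power.t.test`) is one flag away and agrees to well under 0.01
at trial-scale $n$. The published inputs do not state whether the SD
entering the calculation was pooled or control-arm; both conventions are
implemented (pooled is the default) and land within the quoted power
values' tolerance. When group summaries are derived from a fitted model,
the outcome-scale SD is $\sqrt{\sigma_b^2 + \sigma_e^2}$ propagated
through the inverse Box-Cox by the delta method at the class mean.

## Classification tree

The post-hoc tree is plain CART: greedy Gini splits on midpoint
thresholds, children of at least 7 rows, splits attempted only in nodes
of at least 20 rows, and a split kept only if the overall impurity
decrease is at least `cp` times the root impurity. Tie-breaks are
deterministic (variable order, then lower threshold). Importance credits
primary splits only — inputs are complete-case, and surrogate-split
credit (as in the usual recursive-partitioning implementation) inflates
correlated predictors; the usual implementation with surrogates disabled
serves as an independent cross-check in the tests. `cp` is tuned by
class-stratified 10-fold cross-validation on raw accuracy (ties to the
larger `cp`), with balanced accuracy reported as mean ± SE over folds;
the default grid spans 0.0005-0.05, a conventional range for a cohort of
~1600.

## Numerical choices and degenerate inputs

* Per-subject likelihood terms use log-sum-exp over classes; marginal
  covariances use the closed-form Woodbury inverse for the random
  intercept and Cholesky factorization for intercept+slope.
* $\sigma_b = \sigma_e = 0$ is rejected as a degenerate variance;
  variance parameters live on the log scale so zero is approached but
  never crossed.
* Empty-class collapse (a class whose posterior mass vanishes) flags the
  fit and excludes it from grid selection.
* Constant outcome vectors, zero-variance ICV, and volume exactly
  proportional to ICV raise explicit errors rather than silent NaNs.
* All simulation, fold-assignment, and multi-start randomness flows from
  explicit integer seeds through a deterministic stream-splitting helper;
  re-running any stage with the same configuration reproduces outputs
  bit-for-bit (asserted in the pipeline test).

## Problem sizes in the shipped batteries

The recovery and enumeration batteries run at $n = 1000$ subjects with 5
replicate seeds and 2 EM starts per grid cell, and the cross-validation
and tree stages of the demonstration pipeline at $n = 250$-$1000$; these
sizes give stable pass/fail behaviour for the stated thresholds while
keeping a full run of the suite comfortable on a single CPU. The same
thresholds apply unchanged at the full published cohort size.

## Known limitations

* Random intercept only in the class-specific cognitive model (the
  intercept+slope structure is implemented and used for biomarker
  trajectories, G = 1).
* Covariate effects are shared across classes by design; class-specific
  covariate effects are out of scope.
* The bootstrap is not implemented for trajectory bands; the delta
  method is verified against parametric sampling instead.
* Back-transformed class means are the inverse Box-Cox of
  transformed-scale means (a "typical subject" summary), not raw-scale
  refits; with a strongly nonlinear fitted transform these differ from
  arithmetic means on the observed scale.
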