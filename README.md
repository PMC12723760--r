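# cogmix

Latent class mixed-effects modelling of heterogeneous cognitive decline in
preclinical Alzheimer's disease, for biostatisticians designing or
analysing secondary-prevention studies.

Cognitively unimpaired older adults with elevated amyloid decline at very
different rates: in A4/LEARN-type cohorts roughly three quarters stay
cognitively stable over ~7 years of follow-up, while small subgroups
decline slowly or rapidly. `cogmix` implements the full analysis around
that observation:

* **Latent class mixed model (LCMM).** The Box-Cox-transformed Preclinical
  Alzheimer Cognitive Composite (PACC) is modelled as a finite mixture over
  latent classes: class-specific natural cubic spline time effects
  `S(t) α_g`, shared baseline covariate effects `W γ` (treatment arm,
  plasma P-tau217, amyloid PET SUVr, APOE ε4, sex, age, education,
  hippocampal atrophy z-score, test version), a subject random intercept
  `b_i ~ N(0, σ_b²)`, and a multinomial-logit class-membership submodel
  `P(c_i = g | x_i) ∝ exp(ζ_g'x_i)`. Estimation is multi-start EM with a
  monotone log-likelihood; classes are enumerated by BIC/ICL over a grid of
  spline df × number of classes.
* **Posterior classification and baseline-only prediction**, with
  stratified 10-fold cross-validation, precision-recall curves (average
  precision) and balanced accuracy.
* **Class-specific trial power** under attrition, anchored to the
  "maximum possible benefit" of an amyloid-negative stable reference
  group.
* **CART characterization** of the classes from baseline variables (Gini
  splits, cp tuning by CV, impurity-based importance).
* **A synthetic cohort generator** emulating the A4/LEARN design (visit
  schedule, dropout, biomarker-driven membership, published class
  trajectory anchors), so the entire pipeline is testable against known
  ground truth without access to participant data.

## Worked example

```r
library(cogmix)

truth <- preset_a4learn_like()          # study-like generating truth
sim   <- simulate_cohort(truth, n = 1000, seed = 42)

sel <- select_model(sim$cohort, df_grid = 1:3, G_grid = 1:3,
                    n_starts = 2, seed = 1, transform = truth$boxcox)
fit <- sel$best_fit
fit
#> <lcmm_fit> G = 3, spline df = 2, intercept random effects
#>   N = 1000 subjects, loglik = -15877.87, BIC = 32018.24, ICL = 32259.46
#>   class proportions: 0.750 / 0.172 / 0.078
#>   sigma_b = 1.955, sigma_e = 1.265, converged = TRUE (22 iter)
```

The grid selects three classes with two spline degrees of freedom — the
generating configuration — and the fitted class proportions (75/17/8%;
generating mixture 77/16/7%),
random-intercept SD (truth 2.0) and residual SD (truth 1.25) recover the
truth. Back-transformed class mean trajectories
(`class_trajectories(fit)`) land on the generating anchors: the stable
class starts near +0.5 PACC points and improves to ~1.2 by year 6, while
the fast-decliner class falls from ~−1 to ~−16.

Power for a hypothetical trial in amyloid-positive *stable* individuals,
using the published group summaries (means +0.88 vs +1.14, SDs 2.19/2.11
at 2 years; 500 per arm, 10% attrition, α = 0.05):

```r
s2 <- power_scenario(mean_control = 0.88, sd_control = 2.19,
                     mean_reference_max = 1.14, sd_reference = 2.11,
                     n_per_arm = 500, attrition = 0.10, horizon_years = 2)
power_two_sample(s2)
#> [1] 0.4419131
max_benefit(1.14, 0.88)
#> [1] 0.26
```

Even granting the treatment 100% of the maximum possible benefit (0.26
PACC points), such a trial has only ~44% power — stable participants
contribute little information to a cognitive endpoint, which is the
design point the class structure makes quantitative.

One call runs everything end-to-end on a synthetic cohort and writes all
artifacts (selection table, fit JSON, posteriors, baseline summary,
trajectories, CV metrics, power table, tree) plus a reproducibility
manifest:

```r
run_pipeline(pipeline_config(out_dir = "demo_run", simulate_n = 500))
```

## Package layout

| Area | Functions |
| --- | --- |
| Data model & summaries | `read_cohort`, `write_cohort`, `derive_cdr_progression`, `summarize_by_class` |
| Preprocessing | `fit_boxcox`, `build_spline_basis`, `residualize_and_z`, `tau_composite` |
| Simulation | `simulation_truth`, `preset_a4learn_like`, `simulate_cohort` |
| LCMM | `lcmm_spec`, `fit_lcmm`, `lcmm_loglik`, `select_model`, `posterior_probs`, `class_trajectories`, `fit_biomarker_lmm` |
| Evaluation | `make_folds`, `cross_validate`, `predict_class_baseline`, `pr_curve`, `classification_metrics` |
| Power | `power_scenario`, `power_two_sample`, `power_table`, `max_benefit` |
| Trees | `grow_tree`, `tune_tree`, `variable_importance` |
| Orchestration | `pipeline_config`, `run_pipeline` |

The methods vignette (`vignettes/cogmix-methods.Rmd`) documents the model,
the estimation algorithm, every tunable default, what the generator does
and does not emulate, and the package's design decisions.
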