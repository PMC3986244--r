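---
title: "Methods: lipidomic case-control association and cross-validated risk prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lipidomic case-control association and cross-validated risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

lipidcvd implements a complete analysis pipeline for plasma lipidomic
case-control studies of cardiovascular risk under treated HIV infection: a
three-group retrospective design (HIV-positive cases with a future coronary
event, HIV-positive controls, healthy HIV-negative controls) profiled for a
few hundred lipid species grouped into lipid classes. This vignette explains
the models and procedures, the tunable parameters, what the synthetic cohort
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

```{r setup}
library(lipidcvd)
```

## The association model

For each lipid feature (a species, or a class total) and a two-group
contrast, the package fits a multiple binary logistic regression

$$\operatorname{logit} P(y_i = 1) = \beta_0 + \beta_1 x_i + \gamma^\top z_i,$$

where $x_i$ is the feature on the analysis scale and $z_i$ the adjustment
covariates declared in the contrast (for the HIV-vs-healthy contrast the
design covariates are family history of CHD, smoking and hsCRP; for the
case-vs-control contrast, current statin treatment). The effect is reported
as the odds ratio per interquartile-range increase,
$\mathrm{OR} = \exp(\beta_1 \cdot \mathrm{IQR}(x))$, with a Wald 95% CI
$\exp((\beta_1 \pm 1.96\,\mathrm{se})\cdot \mathrm{IQR})$. OR-per-IQR is the
natural effect size for concentration features whose units and dynamic
ranges differ by orders of magnitude across a lipidomics panel.

Numerical choices, all of which matter to the reported OR:

* **Analysis scale.** Concentrations enter as $\log_{10}$ values by default
  (`analysis_scale = "log10"`); lipid concentrations are positive and
  right-skewed, and the IQR is taken on the *same* scale as the fitted
  predictor so the OR-per-IQR is self-consistent. A `raw` scale is
  available. Note that OR-per-IQR is invariant to the base of the
  logarithm, but not to switching between log and raw scales.
* **IQR rule.** Inclusive linear-interpolation quantiles (R's type 7, the
  default). A different quantile rule rescales every OR slightly, so the
  rule is pinned in code rather than left to the caller.
* **IQR basis.** The IQR is computed over the samples entering that fit
  (the two contrast groups), recorded in the output as `iqr_used`.
* **Class totals.** A class feature is the per-sample *sum* of member
  species concentrations (aggregation on the raw scale, configurable to
  the mean), log-transformed afterwards.
* **Multiplicity.** Benjamini–Hochberg step-up adjustment, applied across
  all converged features of the same level within a contrast; species and
  classes form separate families, since they answer questions at different
  resolutions.
* **Separation.** Complete separation is detected as a vanishing binomial
  deviance; such fits are reported with `converged = FALSE` and `status =
  "unconverged"`, excluded from the BH family, and never given a fabricated
  CI. Constant features (`IQR = 0`) are likewise enumerated, not silently
  dropped.

The cohort characteristics table uses Mann–Whitney U tests for continuous
variables (exact enumeration for tie-free samples with $m+n \le 12$,
otherwise the tie-corrected normal approximation with continuity
correction) and Fisher's exact test for binary ones, matching the
conventions of case-control characteristics tables in this field.

## The prediction framework

The prediction task is discriminating HIV cases (future cardiovascular
event) from HIV controls. Three feature sets are supported: lipid species
alone, conventional lipids alone (HDL-C, LDL-C, total cholesterol,
triglycerides), and both combined — the same harness run on different
feature tables (`cv_features()`).

The harness (`run_repeated_cv()`) is a repeated class-stratified $k$-fold
cross-validation: per repeat, samples are partitioned into $k = 3$ folds
preserving the case:control ratio (per class, fold sizes differ by at most
one); each fold serves once as the test set, so 400 repeats yield exactly
1200 trials. Within each trial, using the training two-thirds only:

1. features are centred and scaled to unit SD with training-fold
   statistics (required for a margin-based classifier on concentration
   data; the held-out third is transformed with the same parameters);
2. features are ranked by univariate two-sided discrimination
   $|\mathrm{AUC} - 0.5|$ of the feature against the training labels, ties
   broken lexicographically — anti-discriminating features are as useful to
   a linear classifier (which can negate a weight) as discriminating ones,
   which is why the criterion is two-sided rather than raw AUC;
3. the top $n$ features enter a soft-margin linear SVM
   ($\tfrac12\lVert w\rVert^2 + C\sum_i \xi_i$, $C = 1$ by default, solved
   by libsvm). A linear kernel is the defensible default in the
   $n \ll p$ tabular setting and yields interpretable weights; kernel and
   $C$ are configurable but not searched.

The held-out third is scored with the continuous decision values; AUC is
computed from midranks (identically the scaled Mann–Whitney U), and
accuracy, sensitivity, specificity, PPV and NPV at the margin midpoint
(decision value 0). Undefined ratios (e.g. PPV in a trial with no positive
predictions) are reported as missing, never as zero, and excluded pairwise
during aggregation. Per-metric means carry normal-approximation 95% CIs
($\pm 1.96\,\mathrm{SD}/\sqrt{n}$ over trials); the paper-style tables in
this field do not state their CI construction, so the most common choice is
used and recorded here.

The model size $n^\ast$ is the smallest feature count maximising the mean
cross-validated AUC over candidates $1..n_{\max}$ (`select_model_size()`,
parsimony tie-break; all candidates share fold sequences via a common seed,
making the comparison paired). Feature stability is reported as the
inclusion frequency: the percentage of trials in which each feature entered
the model.

**No leakage, by construction and by test.** Scaling parameters, rankings
and classifiers are functions of the training portion only; the test suite
asserts directly that permuting held-out-fold labels changes no selected
feature set and no trained classifier.

## Risk-equation evaluator

Ten-year coronary-risk comparators are declarative objects: a set of terms
(variable, transform, coefficient), a centering map, and a baseline in one
of two forms — Cox-survival, $r = 1 - S_0^{\exp(L - L_{ref})}$, the
Framingham/Reynolds structure; or log-rate,
$r = 1 - \exp(-e^{L} t)$, the D:A:D structure, where cumulative
antiretroviral exposure enters as years-of-exposure identity terms. The
published coefficient values of named risk scores are *data*, not code:
the package ships structural templates with zero placeholder coefficients
(`inst/extdata/equations/*_template.yaml`) to be filled from the cited
primary sources, plus one synthetic demonstration equation
(`demo_synthetic.yaml`) with invented but physiologically sensible
coefficients used in examples and tests. Discrimination is the
non-cross-validated C-statistic of the per-sample risks against the
observed outcome.

## The synthetic cohort generator

No patient-level data ship with studies of this design, so all development
and testing runs against `generate_cohort()`, which emulates the assumed
statistical structure with *known* injected effects:

* **Design.** 23 HIV cases, 45 HIV controls, 45 healthy controls; 316
  species in 24 classes. The per-class species counts are not published
  anywhere, so the default catalogue is a realistic targeted-panel
  allocation (triacylglycerols and phosphatidylcholines largest; free
  cholesterol a single species) summing to 316.
* **Concentrations.** Log-normal (positivity and right skew, the
  lipidomics convention; the measurement distribution is never stated in
  this literature). Species baselines scatter around `log_mu` with SD
  `species_mu_sd` (default 1, spanning orders of magnitude as real panels
  do); the per-species log-scale SD is `log_sigma` (default 0.5).
* **Correlation.** One shared standard-normal factor per lipid class with
  loading $\lambda$ (default 0.6): within-class correlation of
  log-concentrations is $\lambda^2 = 0.36$, zero across classes. This
  mirrors the coherent class-level behaviour of real panels while keeping
  the ground truth analytic.
* **Covariates.** Distributional models per group (Bernoulli for binary
  variables; normal for age, blood pressure, BMI; log-normal for hsCRP,
  CD4, HDL/LDL/total cholesterol, triglycerides), with medians and
  IQR-derived spreads matching a treated-HIV coronary-risk cohort
  characteristics table. By default all groups share the HIV-control
  distributions, so covariates are independent of group membership and the
  association scans have a clean ground truth; `confounded = TRUE` enables
  the full group-specific distributions (statin use enriched in cases,
  smoking in the HIV groups, and so on) for cohort-table and risk-equation
  work.
* **Effects.** An effect is declared as a target OR per IQR for a species
  or class on one contrast, and injected as a group-conditional mean shift
  on the log scale. For two equal-variance Gaussian populations shifted by
  $\delta$, the induced logistic slope is $\delta/\sigma^2$;
  `shift_from_target_or()` inverts this at a given IQR. Because injecting a
  shift widens the *pooled* two-group IQR beyond the within-group IQR, the
  generator calibrates $\delta$ by fixed-point iteration against the pooled
  mixture IQR (`calibrate_shift()`), so the odds ratio that a downstream
  scan *realises* per sample IQR converges to the declared target — the
  realized OR is an approximately recovered quantity and all tests use
  tolerance bands, not exact equality. A *class-level* effect applies one
  uniform log-shift to every member species (so the raw class total scales
  exactly by $e^\delta$), with $\delta$ calibrated against the SD of the
  log class total, approximated by Fenton–Wilkinson moment matching of the
  correlated log-normal sum. `target_or_for_auc()` maps a target
  single-feature AUC to the OR that realises it.
* **Export.** Raw concentrations by default; a `log10` export scale is
  supported and flagged in the configuration carried by the cohort (CSV
  export always writes raw values so the on-disk schema is unambiguous).

What the generator does **not** emulate: LC-MS measurement error and batch
effects, missingness, age/sex matching structure, antiretroviral
pharmacology, or any real between-class correlation beyond the single
factor. Passing tests therefore demonstrate that the *procedures* are
correct and calibrated under the assumed structure, not that the original
study's empirical values are reproducible — its patient-level numbers
(specific odds ratios, counts of significant species, absolute AUCs) depend
on undeposited data and are out of reach by design.

## Calibration properties and problem sizes

The test suite and the acceptance script verify, at the design scale of
113 samples by 316 species unless noted:

* the 3-fold, 400-repeat harness performs exactly 1200 trials;
* on zero-effect cohorts the species scan's raw $p<0.05$ fraction is
  $0.05 \pm 0.02$ (20 replicate cohorts);
* on zero-effect cohorts the mean cross-validated AUC is $0.5 \pm 0.05$.
  This expectation is estimated over 10–20 independent cohorts (a few
  repeats each) rather than many repeats of one cohort: conditional on a
  single fixed null dataset the CV mean has a cohort-level SD of about
  0.07 — held-out-fold group differences anti-correlate with training-fold
  differences on a fixed dataset, and feature selection amplifies the
  spread — so the per-cohort mean is not the calibrated quantity, the
  over-cohort expectation is;
* an injected OR-per-IQR of 3.72 is recovered within ±15% at 4000 samples
  per arm; an injected single species of AUC ≈ 0.9 is top-ranked and alone
  yields a mean cross-validated AUC ≥ 0.8 (20 repeats);
* BH, AUC, Fisher and the logistic slope agree with independent
  brute-force oracles (min-over-suffix enumeration, pair counting,
  hypergeometric enumeration, the closed-form 2×2 log odds ratio).

One step-up subtlety uncovered by the oracle work: the BH map is *not*
idempotent (re-applying it multiplies by $m/j$ again); the invariant that
does hold — and is tested — is that the sorted adjusted values are already
monotone, so a second monotonisation pass changes nothing.

Repeat counts in the routine test runs are scaled down (tens of repeats)
from the 400-repeat production setting; both settings use the identical
code path, and the trial-accounting check runs the full 1200 trials.

## Worked example

```{r example, eval = FALSE}
cfg <- generator_config(
  seed = 1,
  effects = list(effect_spec("DG", "CASE_vs_CONTROL", 3.72)))
coh <- generate_cohort(cfg)

scan <- association_scan(coh, contrast_spec("HIV_CASE", "HIV_CONTROL",
                                            adjust = "statin"),
                         level = "class")
dplyr::filter(tidy(scan), p_adj < 0.05)
autoplot(scan)

fm <- cv_features(coh, "species")
rep <- cv_report(fm$x, fm$y, cv_config(repeats = 50, max_features = 10,
                                       seed = 1))
glance(rep)
plot_inclusion(rep)
```

## Known limitations

* The generator's single-factor class correlation understates the richer
  covariance of real lipidomes; stability frequencies on synthetic data
  are more optimistic than on correlated real panels.
* Wald CIs and p-values are first-order; at 23 cases per contrast, exact
  or penalised logistic methods would differ in the tails (penalised fits
  are out of scope; separation is flagged instead).
* The SVM penalty is fixed rather than nested-CV-tuned, matching the
  framework being modelled; reported performance is conditional on that
  choice.
* The risk-equation evaluator is variant-agnostic and ships no published
  coefficients; its C-statistics are only as meaningful as the
  coefficients supplied.
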