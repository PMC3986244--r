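# lipidcvd

Lipidomic case-control association and cardiovascular risk prediction for
treated HIV cohorts.

HIV-positive patients on antiretroviral therapy carry roughly double the
coronary risk of the general population, and standard lipid panels (HDL-C,
LDL-C, total cholesterol, triglycerides) do not capture the complex
dyslipidaemia induced by the virus and its treatment. Plasma lipidomic
profiling measures hundreds of individual lipid species across classes
(ceramides, phospholipids, glycerolipids, sterol esters, ...) and offers a
richer substrate both for characterising HIV-associated lipid changes and
for predicting future cardiovascular events. `lipidcvd` is an R package for
exactly this analysis pattern: a three-group case-control design
(HIV-positive cases with a future coronary event, HIV-positive controls,
healthy controls), a sample-by-species concentration matrix, and clinical
covariates. It is aimed at biostatisticians and computational lipidomics
researchers who need the full pipeline — association scans, cross-validated
risk models with feature-stability reporting, and risk-equation comparators
— with a calibrated synthetic-cohort generator for method validation, since
patient-level data from such studies are typically not deposited.

## What it computes

**Association scans.** Per lipid species or class, multiple binary logistic
regression of group membership on the log10 concentration plus adjustment
covariates; effects reported as the odds ratio per interquartile-range
increase,

    OR = exp(beta * IQR),  95% CI = exp((beta +/- 1.96 se) * IQR),

with Benjamini–Hochberg FDR control across each feature family, and a
cohort characteristics table (median (IQR) / % with Mann–Whitney U and
Fisher's exact comparisons).

**Cross-validated prediction.** A repeated class-stratified 3-fold
cross-validation harness: within each trial, features are centred/scaled
with training-fold statistics, ranked by univariate |AUC − 0.5| against the
training labels, and the top *n* enter a soft-margin linear SVM; the
held-out fold is scored for accuracy, ROC AUC, sensitivity, specificity,
PPV and NPV. 400 repeats × 3 folds = 1200 trials, aggregated to means with
95% CIs, an AUC-versus-model-size curve (the chosen size n\* is the
smallest maximising mean AUC), and per-feature inclusion frequencies (a
stability measure).

**Risk-equation comparators.** A declarative evaluator for 10-year CHD risk
equations in Cox-survival form (risk = 1 − S0^exp(L − L_ref); Framingham /
Reynolds structure) or log-rate form (risk = 1 − exp(−exp(L)·t); D:A:D
structure with antiretroviral-exposure terms), defined in YAML, scored as
non-cross-validated C-statistics. Published coefficients are configuration,
not code: structural templates ship under `inst/extdata/equations/`.

**Synthetic cohorts.** `generate_cohort()` emulates the study design (23
HIV cases / 45 HIV controls / 45 healthy controls; 316 species in 24
classes; within-class factor correlation; Table-1-style covariate
distributions) with effects injected as calibrated log-scale mean shifts
parameterised by the OR-per-IQR they should realise.

## Worked example

```r
library(lipidcvd)

cfg <- generator_config(
  seed = 1,
  effects = list(effect_spec("DG", "CASE_vs_CONTROL", 3.72)))
coh <- generate_cohort(cfg)   # 113 samples x 316 species, 24 classes

scan <- association_scan(coh,
  contrast_spec("HIV_CASE", "HIV_CONTROL", adjust = "statin"),
  level = "class")
dplyr::filter(tidy(scan), p_adj < 0.05)
#> # A tibble: 1 × 6
#>   feature_id or_per_iqr ci95_low ci95_high    p_raw  p_adj
#> 1 DG               7.92     2.49      25.3 0.000467 0.0112
```

The diacylglycerol class — the one carrying an injected odds ratio of 3.72
per IQR — is the only class passing FDR control; at 23 cases vs 45 controls
the point estimate (7.9) is noisy, but the 95% CI covers the generative
value, and at 4000 samples per arm the scan recovers 3.72 within a few
percent (that recovery is one of the package's calibration checks).

```r
fm  <- cv_features(coh, "species")
rep <- cv_report(fm$x, fm$y,
                 cv_config(repeats = 50, max_features = 10, seed = 1),
                 size_repeats = 10)
glance(rep)
#> # A tibble: 1 × 6
#>   n_star n_trials mean_auc auc_ci95_low auc_ci95_high mean_accuracy
#> 1      3      150    0.705        0.688         0.722          66.6
head(rep$inclusion, 5)
#> # A tibble: 5 × 4
#>    rank feature_id count frequency
#> 1     1 DG_09        119      79.3
#> 2     2 DG_05         79      52.7
#> 3     3 DG_08         72      48
#> 4     4 DG_06         53      35.3
#> 5     5 TG_22         20      13.3
```

The size search settles on a 3-feature model with mean cross-validated AUC
0.705 (95% CI 0.688–0.722) and 66.6% accuracy; the most stably selected
features are diacylglycerol species — the injected signal class — with the
top species entering 79% of the 150 trials. `autoplot(rep)` draws the
AUC-versus-size curve and `plot_inclusion(rep)` the stability barplot.

An end-to-end run (cohort CSVs, Table-1/2-style association TSVs,
Table-3/4-style CV TSVs, per-trial audit file, risk-equation scores, a
combined text report; all stamped with seed and config hash and
byte-identical under a fixed seed) is one call:

```r
run_pipeline("out", pipeline_config(seed = 1))
```

or, from a shell, via the thin wrapper `inst/cli/lipidcvd.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","lipidcvd.R",package="lipidcvd"))')" \
  all --out out --seed 1
```

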