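# pdacgrowth

Growth-kinetics and metabolic-profile analysis of pancreatic ductal
adenocarcinoma (PDAC) in the pre-diagnostic period, for researchers working
with serial CT measurements of pancreatic lesions — typically patients in
whom PDAC arose as a second primary cancer and was caught on follow-up scans
for the first one.

Imaging-defined PDAC subtypes ("high delta" tumors with a conspicuous
tumor–parenchyma interface on contrast CT versus inconspicuous "low delta"
tumors) differ in biology and outcome. This package asks how they differ
*before* diagnosis: in growth rate, in projected initiation time, and in the
systemic wasting and glucose disturbance they cause.

## What it computes

**Growth model.** Each lesion's serial biaxial measurements become volumes
(geometric-mean diameter, sphere approximation) and are fitted with the
Gompertz law

    X(t) = K · exp( ln(X0/K) · e^(−αt) )

with the carrying capacity fixed at K = 180 cm³ (a 7-cm sphere) and X0
anchored at the first observed volume, so the growth-rate constant α
(month⁻¹) is the single free parameter, estimated by Levenberg–Marquardt
nonlinear least squares. 1/α is the characteristic growth time.

**Initiation time.** The fitted curve is projected backward to the time to
grow from a single cell (10⁻⁶ mm³) to a detectable 10 mm³ mass (10⁷ cells);
the projection is independent of X0 and equals (1/α)·ln[ln(Xs/K)/ln(Xe/K)].
Per-class initiation times are characterized by a maximum-likelihood
lognormal distribution (mode, quantiles, CDF).

**Classification.** α is used to classify the delta class: ROC/AUC built
directly on α (identical to the ROC of the monotone logistic model),
accuracy-maximizing discrimination threshold, confusion metrics including the
Matthews correlation coefficient, complementary cumulative distribution
curves, and leave-one-out cross-validation.

**Metabolic profile.** Single-slice body-composition volumes (subcutaneous
fat, visceral fat, muscle) yield per-patient wasting rates (% change/month);
blood-glucose series yield pre-diagnostic OLS slopes; classes are compared by
Welch's t-test.

**Synthetic cohorts.** No patient data are distributed; `generate_cohort()`
produces cohorts with the study's statistical structure (29 high / 26 low
delta, class-mean α of 0.088 / 0.024 month⁻¹, irregular scan schedules,
measurement noise, class-specific wasting and glucose trends) plus a
ground-truth table for recovery testing; `null_cohort()` provides
label-independent cohorts for null calibration.

## Worked example

```r
library(pdacgrowth)

cohort <- generate_cohort(cohort_config(seed = 1))
cohort
#> PDAC cohort: 55 patients (29 high delta, 26 low delta)
#> Lesion observations per patient: 2-6 (median 4)
#> Tissue series: 55 patients; BG series: 55 patients

report <- run_pipeline(cohort)
report
#> Pre-diagnostic PDAC growth-kinetics report
#>   55 patients fitted, 0 excluded
#>   low delta (n = 26): mean alpha 0.0260 month^-1, characteristic time 38.5 months
#>     initiation time: mode 18.4 months, 90% quantile 23.5 years
#>   high delta (n = 29): mean alpha 0.0985 month^-1, characteristic time 10.2 months
#>     initiation time: mode 6.8 months, 90% quantile 3.2 years
#>   pooled fit quality (Pearson R): high 0.995, low 0.994
#>   classifier: AUC 0.875, threshold 0.0251 month^-1, accuracy 85.5%, MCC +0.71
#>   LOOCV: pooled accuracy 81.8%, training AUC 0.875 +/- 0.007
#>   muscle wasting: -8.9 (high) vs -0.2 (low) %/month, p = 5e-23
#>   SAF wasting: -8.7 (high) vs -0.7 (low) %/month, p = 1.1e-19
#>   VAF wasting: -10.4 (high) vs -1.0 (low) %/month, p = 1.2e-23
#>   BG slope: 1.82 (high) vs 0.35 (low) mg/dL/month, p = 1.2e-06
```

Reading this: the fitted class-mean growth rates (0.026 vs 0.098 month⁻¹)
recover the generating means (0.024 / 0.088) up to sampling noise at n = 55;
the growth-rate constant alone classifies the subtype with AUC 0.875 and a
cross-validated accuracy of 82%; and high delta patients lose soft tissue
roughly an order of magnitude faster while their glucose rises. Individual
fits are regular S3 model objects:

```r
fit <- fit_gompertz(cohort$patients$P001)
fit
#> Gompertz growth fit for patient P001
#>   alpha = 0.0314 month^-1 (characteristic time 31.9 months)
#>   X0 = 1236.1 mm^3 (anchored), K = 180000 mm^3 (fixed)
#>   2 observations over 5.0 months, Pearson R = 1.0000
coef(fit); predict(fit, 0:12); plot(fit)
```

Real measurements come in through CSV (`read_cohort()`; schemas in its help
page), and `run_pipeline(cohort, out_dir = "...")` writes per-patient fit and
rate tables plus a JSON report.

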