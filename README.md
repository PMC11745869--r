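# dexhdi

Risk modelling of dexmedetomidine-associated hemodynamic instability in
pediatric anesthesia.

Intranasal dexmedetomidine (DEX, 3 µg/kg) is a popular premedication for
children, but its α2-agonist activity causes hypotension and bradycardia in a
substantial fraction of patients. `dexhdi` implements, as reusable and tested
R functions, an end-to-end analysis of which clinical, pharmacokinetic and
pharmacogenetic factors drive the time to the composite endpoint
*hemodynamic instability* — a drop of more than 20% from the age-specific
baseline in systolic/diastolic blood pressure (hypotension) and/or heart
rate (bradycardia) — over the first 90+ minutes after DEX administration.

The pipeline is aimed at clinical pharmacologists and biostatisticians and
consists of:

1. **Population PK engine** (`poppk_model`, `map_estimate`,
   `derive_metrics`): a two-compartment model with first-order absorption
   and apparent (CL/F-style) parameters,

   CL/F = 53.0 · (W/70)^0.75 · PMA³ / (PMA³ + 44.7³)  [L/h],
   V/F = 57.5 · (W/70), Q/F = 243.8 · (W/70)^0.75, V₂/F = 71.8 · (W/70),

   with weight in kg and postmenstrual age (PMA) in weeks. Individual
   parameters are obtained by MAP (empirical-Bayes) estimation from sparse
   samples — here a single 60-min plasma level — maximizing
   −½Σ(log c_obs − log c_pred)²/σ² − ½Ση²/ω².
2. **Genetics** (`compute_maf`, `hwe_chi2`, `encode_genotype`): allele
   frequencies, Hardy–Weinberg χ² tests and
   dominant/recessive/overdominant/additive contrasts for candidate SNPs in
   DEX metabolism (*CYP2A6*, *UGT2B10*, *NR1I2*) and drug-response
   (*ADRA2B*, *CACNA2D2*, *CACNB2*) genes.
3. **Survival core** (`cox_fit`, `km_estimate`, `ph_test`, `fdr_adjust`,
   `detect_events`): an own Newton–Raphson Cox partial-likelihood solver
   with Efron ties and `(start, stop]` time-dependent covariates (propofol
   induction as a switch), Kaplan–Meier estimation with Greenwood limits,
   Schoenfeld-residual PH diagnostics, and Benjamini–Hochberg screening.
4. **Variable selection** (`split_cohort`, `selection_frequency`,
   `progressive_addition`): 60/40 split, repeated five-fold cross-validated
   LASSO-Cox (via glmnet) with per-fit selection frequencies, and
   progressive addition of frequency-ranked variables until the test-cohort
   AuROC stalls.
5. **Risk model** (`build_nomogram`, `roc_auc`, `youden_threshold`,
   `calibration_curve`): a Cox-derived nomogram (0–100 point scale, Breslow
   baseline risk at a 90-min horizon), Youden-index thresholding and
   bootstrap calibration curves.
6. **Synthetic cohort generator** (`cohort_config`, `generate_cohort`,
   `calibrate_baseline`): a fully parameterized emulation of a 270-child
   interventional-surgery cohort, with the baseline hazard calibrated so the
   marginal Kaplan–Meier curve reproduces the study landmarks (8.2%
   cumulative incidence at 22 min, 16.30% at 90 min, 35-min median
   first-event time, 52/270 affected subjects). It drives every test and
   demonstration without any clinical data.

## Worked example

```r
library(dexhdi)

co   <- generate_cohort(cohort_config(), seed = 20260921)
co
#> Synthetic cohort: n = 270 (seed 20260921); 48 events (17.8%); median weight 11.7 kg

sdat <- cohort_survival_data(co)
km   <- km_estimate(sdat)
100 * km_at(km, c(22, 90), "cuminc")
#> 8.1% at 22 min, 14.5% at 90 min   (this cohort's draw of the 8.2% / 16.3% truth)

fit <- cox_fit(sdat, c("weight_z", "cl_z", "rs8192733", "rs10764319"))
fit
#> Cox proportional hazards fit (efron ties): n = 521, events = 48
#>   covariate    coef    se    hr lower95 upper95       z  p_value
#>    weight_z  0.1559 0.217 1.169   0.764   1.788  0.7189 4.72e-01
#>        cl_z  0.0176 0.208 1.018   0.678   1.529  0.0849 9.32e-01
#>   rs8192733 -1.4167 0.294 0.243   0.136   0.431 -4.8195 1.44e-06
#>  rs10764319  0.4789 0.295 1.614   0.905   2.879  1.6220 1.05e-01
```

The protective *CYP2A6*-like variant (generator truth HR 0.28) is recovered
at HR 0.243 (95% CI 0.136–0.431); the clinical effects are too small to
resolve at n = 270, which is precisely why the full pipeline screens with
FDR control and stability selection. A nomogram then turns the fit into a
bedside score:

```r
nom <- build_nomogram(fit, sdat, horizon = 90)
nom
#> Cox-derived nomogram (risk horizon 90):
#>   covariate    beta   min  max   ref points_per_unit max_points
#>    weight_z  0.1559 -2.47 2.02 -2.47           11.01      49.45
#>        cl_z  0.0176 -3.72 2.66 -3.72            1.24       7.94
#>   rs8192733 -1.4167  0.00 1.00  1.00         -100.00     100.00
#>  rs10764319  0.4789  0.00 1.00  0.00           33.80      33.80
```

Individual PK from a single 60-min sample (0.43 ng/mL after a 33-µg dose in
an 11-kg, 22-month-old child):

```r
m   <- poppk_model()
ind <- map_estimate(m, obs_time = 1, obs_conc = 0.43, dose = 33,
                    weight = 11, pma = pma_from_age(22))
derive_metrics(ind, dose = 33)
#> CL/F 12.4 L/h (1.13 L/h/kg), cmax 0.48 ug/L at 1.88 h, t1/2 1.63 h,
#> AUCinf 2.65 ug*h/L
```

The whole analysis — MAP PK for every subject, genetics summary, univariate
FDR screen, split, LASSO selection, final model, nomogram, ROC/Youden and
calibration — runs as one call:

```r
res <- run_pipeline(co, pipeline_config(seed = 1), output_dir = "out")
```

## Vignette

`vignettes/dexhdi-methods.Rmd` documents the model assumptions, the
generator's calibration strategy and its limitations, numerical choices and
design decisions.
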