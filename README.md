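# ibmscore

CT imaging-biomarker (IBM) survival signatures for oesophageal cancer,
re-implemented as a tested R workflow over synthetic cohorts.

Patients with oesophageal squamous cell carcinoma treated with definitive
chemoradiotherapy have widely varying outcomes, and pre-treatment
contrast-enhanced CT of the primary tumour carries prognostic signal
beyond stage.  This package implements the full quantitative-imaging
pipeline that turns a delineated tumour volume into an individual risk
estimate:

* **96 radiomic features** per (volume, mask) pair on the native
  anisotropic grid — 24 first-order intensity statistics, 20 geometric
  descriptors (volume, exposed-face surface area, sphericity
  π^(1/3)(6V)^(2/3)/A, PCA axis lengths, ...), and 52 texture features
  from the four grey-level matrices (GLCM 20, GLRLM 16, NGTDM 5,
  GLSZM 11), computed on a discretised ROI with 13-direction pooling;
* **three-rule pre-selection**: univariable Cox screen (Wald p < 0.25),
  correlation pruning (|r| ≥ 0.8 keeps the smaller screening p),
  VIF audit;
* **LASSO-Cox signature**: L1-penalised Cox over a log-spaced λ grid, λ
  at the minimum 10-fold cross-validated partial-likelihood deviance; the
  IBM score is the log-partial hazard plus the smallest 0.1-multiple
  constant making training scores positive.  The two published scoring
  formulas (11 terms + 2.5 for overall survival; 8 terms − 1.4 for
  progression-free survival) ship frozen in `published_formula()`;
* **evaluation**: Harrell's C with bootstrap CIs, time-dependent ROC
  (cumulative-case/dynamic-control, KM censoring weights), Youden-index
  cutoffs learned on training and applied to validation, Kaplan–Meier /
  log-rank stratification, multivariable Cox with backward
  likelihood-ratio elimination, cohort balance tests;
* **nomogram + decision curves**: Breslow-baseline individual survival
  prediction S(t|x) = exp(−H₀(t)e^{βx}) and survival-weighted net-benefit
  curves against treat-all/treat-none.

Because no patient imaging is publicly available, the package includes a
first-class synthetic generator (`generate_cohort()`): ellipsoidal CT
phantoms with correlated Gaussian texture and exponential survival whose
hazard is driven by tumour size and texture coarseness, so the whole
chain is testable and planted effects are recoverable.

## Worked example

```r
library(ibmscore)

# one synthetic tumour on a 1 x 1 x 3 mm planning-CT grid
p  <- tumour_params(semi_axes_mm = c(8, 10, 12), spacing_mm = c(1, 1, 3))
tm <- generate_tumour(p, seed = 42)
f  <- extract_all(tm$volume, tm$mask)
length(f)                        # 96
round(f[c("Sphericity", "Major_axis_length", "Coarseness_NGTDM")], 3)
#>        Sphericity Major_axis_length  Coarseness_NGTDM
#>             0.674            21.027             0.005

# the frozen overall-survival formula: 11 terms, constant +2.5
os <- published_formula("OS")
ibm_score(setNames(numeric(11), names(os$terms)), os)
#> [1] 2.5
```

The `analysis/` directory is the study replica as numbered drivers —
`01_simulate_cohort.R` (154 synthetic patients), `02_extract_features.R`,
`03_preselect_and_fit.R` (99/55 split, cascade, LASSO),
`04_evaluate_score.R`, `05_nomogram_dca.R` — each a thin narrative over
the package functions, writing tables under `results/`.  A
representative run prints:

```
univariable screen: 65 / 96 kept at p < 0.25
correlation pruning removed 54, retained 11
lambda_min = 0.0807 (log = -2.517), 5 nonzero terms
score constant: +1.3
training   C-index: 0.738 (95% CI 0.670-0.805)
validation C-index: 0.709 (95% CI 0.610-0.793)
training split:   HR 5.56 (95% CI 3.06-10.09), log-rank p = 5.3e-10
validation split: HR 2.72 (95% CI 1.31-5.64),  log-rank p = 0.0052
score-based model dominates the stage surrogate for thresholds 0.30-0.81
```

i.e. the pipeline recovers the planted size + texture effect on held-out
patients, stratifies risk significantly at the training-derived Youden
cutoff, and the score-based decision curve beats a coarsened stage
surrogate over the clinically relevant threshold range.

See `vignettes/ibm-score-methods.Rmd` for the model, the conventions
fixed where the source description is silent, and known limitations.

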