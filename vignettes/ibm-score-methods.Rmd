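---
title: "Imaging-biomarker survival signatures: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imaging-biomarker survival signatures: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ibmscore` re-implements, as a tested pipeline over synthetic cohorts, a
contrast-enhanced-CT imaging-biomarker (IBM) workflow for survival
prognosis in oesophageal squamous cell carcinoma treated with definitive
chemoradiotherapy: 96 radiomic features per delineated tumour, a
three-rule pre-selection cascade, a LASSO-Cox risk score, Youden-cutoff
risk stratification, nomogram prediction and decision-curve analysis.
This vignette records the modelling conventions and the design decisions
taken where the workflow's published description leaves them open.

## The synthetic cohort generator

No imaging accession accompanies the published study, so every stage here
is exercised on synthetic data whose generator is itself first-class,
tested code.

**Tumour phantoms.** A patient's tumour is an ellipsoid discretised onto
an anisotropic grid: a voxel belongs to the mask iff its centre satisfies
the ellipsoid inequality in physical (mm) coordinates.  In-mask intensity
is a mean enhancement level plus a stationary Gaussian random field:
white noise convolved with an isotropic (in mm) Gaussian kernel of width
`smoothing_sigma_mm`, rescaled by the kernel's L2 norm so the marginal SD
stays at `noise_sd` whatever the correlation length.  The smoothing width
is therefore a pure texture-coarseness dial — NGTDM coarseness responds
monotonically to it (a tested property) — which is exactly what a texture
family needs in order to be informative by construction.  Outside the
mask the volume is a single constant; since every feature is
mask-restricted, a test asserts that changing this background changes
nothing.

**Default acquisition and anatomy.** Spacing is 1.0 × 1.0 mm in-plane
with slice thickness drawn per patient from {3, 5} mm, the two planning-CT
protocols the workflow targets; no resampling is ever applied.  Default
parameter ranges (uniform per patient) are chosen to resemble
oesophageal primaries on contrast-enhanced CT: transverse semi-axes
10–16 mm, cranio-caudal semi-axis 15–35 mm (tumours elongated along the
oesophagus), enhancement 50–70 HU, noise SD 8–15 HU, correlation length
0.5–3 mm.  Every semi-axis must exceed twice the largest spacing so masks
are non-degenerate.

**Survival.** Event times are exponential with rate
`baseline_rate * exp(lp)` — a constant-hazard Cox model, so proportional
hazards holds *exactly* and parameter-recovery tests are clean.  The
default baseline is `log(2)/43` per month (a 43-month median, the order
observed in this disease), with censoring the minimum of a 72-month
administrative horizon and a uniform drop-out draw.  The linear predictor
is a configured combination of *standardised generative parameters*
(major semi-axis, texture correlation length), so specific geometric and
texture features are prognostic by construction and a fitted signature
has a truth to recover.

**What the generator does not emulate**: real anatomy and organ context,
partial-volume and reconstruction-kernel effects, inter-observer
delineation variability, non-proportional hazards and competing risks.
Passing tests therefore demonstrate correctness of the machinery and
recoverability of planted effects, not clinical performance on real
cohorts.

## The 96-feature catalogue

The published workflow fixes the census — 24 intensity, 20 geometric and
52 texture features (GLCM 20, GLRLM 16, NGTDM 5, GLSZM 11) — and names
thirteen members through its two scoring formulas; the remaining members
are filled with the standard radiomics definitions for each family.  The
registry (`feature_registry()`) is data-driven and asserts the census at
every build.  This reconstruction is an explicit assumption: the original
96-member list is not published.

Conventions, fixed and mirrored exactly by the brute-force test oracles:

* **Discretisation** — the grey-level scheme is unstated in the source
  description, so the default is fixed bin *number* (N = 32) computed on
  in-mask intensities, which is stable across the generator's intensity
  ranges; fixed bin width is available.  Constant ROIs get Ng = 1.
* **Geometry in physical units** — volume is voxel count × voxel volume;
  surface area counts exposed voxel faces (exactly testable on boxes, a
  known systematic offset versus meshed surfaces); sphericity is
  π^(1/3)(6V)^(2/3)/A; axis lengths are 4·√eigenvalue of the
  physical-coordinate covariance of voxel centres.
* **Texture neighbourhoods** — the 13 unique grid offsets at Chebyshev
  distance 1, direction weights all 1, ignoring physical anisotropy; this
  matches common practice when no resampling is done and is a documented
  limitation.
* **Aggregation** — GLCM and GLRLM counts are pooled over all 13
  directions into one matrix *before* features are computed, rather than
  averaging per-direction features.  One defensible choice, fixed
  everywhere including the oracles.
* **Degenerate statistics** — single-voxel ROIs return zero dispersion /
  skewness / kurtosis and zero axis lengths with a `degenerate` flag
  instead of failing the patient; a perfectly uniform ROI maps the
  NGTDM coarseness singularity to 10⁶.

## Pre-selection and the LASSO-Cox score

The three-rule cascade is fitted on the training cohort only:

1. univariable Cox per standardised feature, keep Wald p < 0.25 (no
   multiplicity correction at this deliberately liberal stage);
2. among kept features, repeatedly delete the feature with the largest
   univariable p that is still in some pair with |Pearson r| ≥ 0.8, until
   no such pair remains (the published rule states the pairwise deletion
   but not the order; greedy largest-p elimination is deterministic and
   reproduces the stated pairwise behaviour; p-ties break by registry
   order).  VIFs of the survivors are reported as a collinearity audit;
3. LASSO-Cox over a 100-point log-spaced λ grid (four decades below the
   all-zero λ), λ chosen at the minimum 10-fold cross-validated partial
   likelihood deviance, folds stratified by event status and seeded.

Whether the original analysis screened raw or standardised features is
unstated; features here are standardised with training statistics before
every model fit, which LASSO penalisation effectively requires.  For the
same reason the two *published* formulas (11 OS terms with constant +2.5;
8 PFS terms with constant −1.4) are interpreted as acting on standardised
features: applied to raw HU-scale inputs, a coefficient like −3.231 on an
upper intensity percentile would dwarf the +2.5 constant.  The frozen
coefficients are carried verbatim either way.

The fitted score is the penalised model's log-partial hazard plus a
constant, chosen as the smallest multiple of 0.1 that makes every
*training* score strictly positive — one concrete reading of the
published "constant used to obtain scores > 0", consistent with its
printed value (a training minimum of −2.43 yields +2.5).  Fitted
formulas embed their scaling so they are self-contained JSON artefacts.

## Evaluation machinery

* **Concordance** — Harrell's C over usable pairs (earlier time must be
  an event; tied times usable only for event/censored pairs with the
  event first; tied scores count ½), with a seeded percentile bootstrap
  (default 1000 resamples) for the CI.  Cross-checked in tests against
  both a loop-enumeration oracle and `survival::concordance`.
* **Time-dependent ROC** — the estimator is unnamed in the source, so the
  standard cumulative-case / dynamic-control form with Kaplan–Meier
  inverse-censoring weights is used; AUC by trapezoid.  The Youden cutoff
  maximises J = sens + spec − 1, ties resolved toward higher specificity,
  returned as the midpoint between adjacent observed scores; it is
  learned on the training cohort and applied unchanged to validation.
* **Multivariable Cox** — both a full fit and backward likelihood-ratio
  elimination are provided (removal threshold p > 0.10, the conventional
  stepwise default), because published per-covariate p-values are
  ambiguous about which stage they report.
* **Balance tests** — pooled-variance t-test for continuous variables,
  Pearson chi-squared without continuity correction for categorical ones;
  the latter reproduces the published training/validation sex comparison
  (p = 0.841) exactly.

## Nomogram and decision curves

Individual prediction uses a univariable Cox fit on the score with a
Breslow baseline (the standard pairing with partial-likelihood fits):
S(t|x) = exp(−H₀(t)·e^{βx}).  The points scale is the affine 0–100 map
over the training score range.  Median survival is reported only within
follow-up ("not reached" otherwise); no parametric extrapolation.

Decision curves use the survival-weighted form: at threshold probability
p_t, "positive" means predicted risk ≥ p_t, the event probability among
positives by the horizon is a Kaplan–Meier estimate *within the positive
group* (handling censoring, which any 5-year oesophageal endpoint has),
and net benefit is (n₊/n)[risk₊ − (1−risk₊)·p_t/(1−p_t)].  Whether the
original analysis used binary or survival-weighted DCA is not described;
the survival-weighted choice is the defensible one for censored
endpoints and reduces to the textbook closed form on uncensored data (a
tested identity).

## Pipeline hygiene and reproducibility

`run_pipeline()` sequences simulate → extract → split (99:55 by default)
→ pre-select → fit → score → evaluate → nomogram/DCA.  Scaling,
screening decisions, λ, the score constant, the Youden cutoff and the
nomogram baseline are all learned on the training cohort and applied
frozen to validation; the report carries a stage-by-stage lineage record
so leakage is auditable.  All randomness flows from three named seeds
(simulation, folds, bootstrap); identical configs give identical
reports.  If the cross-validated LASSO shrinks every coefficient away
(typical under a null configuration), the signature is constant: the
report flags `all_zero`, concordance evaluates at exactly 0.5, and the
scoring-dependent stages are skipped rather than fabricated.

## Problem sizes used by the test-suite experiments

Parameter-recovery experiments run at the sizes a desk-scale replica
supports: selection recovery uses 20 seeds of n = 300 feature-level
cohorts (3 planted among 30 noise features); end-to-end generalisation
uses 5 seeds of n = 300 imaging cohorts with a strong planted size +
texture effect (3 mm slices, transverse semi-axes 6–14 mm) and requires
held-out C-index > 0.65; null-configuration checks use 5 seeds at the
study's n = 154 with the chance band asserted on the seed-mean (a single
55-patient validation C-index is too noisy for a tight per-seed band),
plus a tighter per-seed band at the signature level where an n = 500
independent test cohort is cheap.  Texture implementations are verified
against brute-force enumeration oracles on 50 random ROIs (≤ 6³ voxels,
≤ 4 grey levels) at 10⁻¹⁰ relative tolerance.

## Known limitations

Anisotropy-blind texture offsets; face-counting surface area's systematic
offset; the reconstructed (not published) feature catalogue beyond the
thirteen named members; standardised-feature interpretation of the
published formulas; no competing risks, time-varying covariates or
proportional-hazards diagnostics; no DICOM ingestion (NIfTI only); no
wavelet/filtered-image or 2D feature variants.
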