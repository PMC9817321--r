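---
title: "Functional lung volumetry and postoperative prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional lung volumetry and postoperative prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungflv)
```

## The measurement model

Calibrated CT expresses tissue density in Hounsfield units: air ≈ −1000,
water 0, soft tissue ≈ +40. Aerated lung sits in between, and its HU tracks
the air fraction of each voxel. Two inclusive windows define the pipeline's
quantities:

* **TLV window, [−1024, −500] HU.** Everything that is recognisably lung
  (air through poorly aerated parenchyma). Applied per voxel with no
  morphology, then cleaned in three steps: voxels face-connected to the grid
  boundary are removed as exterior air; the tracheal air column is removed by
  Boolean subtraction; connected components below 50 mL are dropped as noise
  islands. The result is the total-lung mask, and its volume (voxel count ×
  voxel volume) is the TLV.
* **FLV window, [−910, −600] HU.** Normally aerated, functional parenchyma.
  Tissue below −910 HU is hyperinflated (emphysema, air trapping) and
  contributes little gas exchange; tissue above −600 HU is consolidated,
  fibrotic or tumour and contributes none. The functional mask is the
  intersection of this window with the TLV mask, so FLV ⊆ TLV holds by
  construction.

Windows are closed intervals. This is the least surprising reading of a
range quoted with plain endpoints, and the choice is visible (and
overridable) in `threshold_window()`.

Lobar volumetry intersects the FLV mask with an integer lobe label map
(1 = RUL … 5 = LLL). Fissure detection itself is out of scope: label maps
come either from the phantom's generative geometry or from the user. FLV
voxels without a label are reported as *unassigned*, excluded from lobe sums
but kept in the total, with a warning above 5%.

## Prediction methods

All three predictors scale or regress preoperative spirometry (litres):

* FLV method: `pre × (1 − resected FLV / total FLV)`, the total being both
  lungs' preoperative FLV.
* Segment counting: `pre × (1 − n/19)` with the fixed 3/2/5/5/4 lobe table.
  It is undefined for non-anatomic (wedge) resections, so
  `resected_segment_count` is `NA` there and the prediction propagates `NA`.
* Regression equations with fixed coefficients
  (`regression_coefficients()`): `postFVC = 0.8·preFVC − 0.784·Δ + 0.283`
  (residual SD 0.338 L), `postFEV1 = 0.766·preFEV1 − 0.694·Δ + 0.22`
  (residual SD 0.265 L), where Δ = ΔFLV/FLV is the functional loss ratio.
  Coefficients are data, not code: a refit from `ols_fit()` can be swapped
  in without touching the pipeline.

**The Δ ambiguity.** "Ratio of reduced FLV to preoperative FLV" admits two
readings: the preoperative FLV of the resected lobes over the preoperative
total ("resected-lobe"), or the drop in total FLV between two scans over the
preoperative total ("pre-post"). Both are implemented
(`delta_flv_ratio(mode = )`); resected-lobe is the default because it needs
one scan. In pre-post mode a negative drop — the remaining lung expands
after surgery, which real series do show — is clipped to 0 for the
predictor, with the raw value logged, because the regression was fitted on
reduction ratios.

## Segmentation internals

* **Airway.** Region growing through the 26-connected component of voxels
  ≤ −950 HU from a seed. The auto-seed scans the most superior 10% of
  slices for an in-plane air component that does not touch the slice border
  (exterior air always does) and whose centroid lies in the central third of
  both in-plane axes — i.e. the trachea. A leak guard stops growth when one
  slice's component area more than triples the previous slice's while
  descending; the trigger is logged. The −950 HU cutoff, the connectivity
  and the tripling factor are arguments, since proprietary clinical tools do
  not document their equivalents.
* **Connectivity conventions.** 26-connectivity for airway growth and lung
  components (permissive, keeps thin structures together); face (6-)
  connectivity for exterior-air removal so a diagonal pinhole in the body
  wall cannot leak the exterior into the lung. Labelling is a compiled
  flood fill (`src/components.cpp`).
* **Degenerate inputs.** HU outside [−1024, 3071] is clipped on
  construction (calibration artifacts, with a warning); missing spacing is
  an error, never defaulted; an empty lung after cleaning raises a typed
  error, as does an unfindable airway seed (callers may proceed with an
  empty airway, and the pipeline does, with a warning).

## What the phantom emulates — and what it does not

`build_phantom()` rasterises ellipsoidal lungs inside a soft-tissue body
cylinder surrounded by exterior air, a tracheal air column entering at the
apex, planar fissures (oblique + horizontal on the right, oblique on the
left) giving analytic lobe membership, and spherical disease blobs. HU is
drawn i.i.d. per tissue class: parenchyma N(−750, 50), emphysema
N(−960, 15), consolidation N(−100, 60), body +40, air −1000.

Defaults describe a reduced-scale thorax — 1 mm isotropic voxels on a
192×128×192 grid, each lung ≈ 0.6 L — chosen so a full phantom builds and
segments in seconds; all geometry scales through `phantom_spec()`. The
default disease burden is mild: ≈ 2–3% emphysema and < 0.5% consolidation
of lung volume. Consolidation is deliberately the smaller class because it
is excluded from the TLV mask itself (it lies above −500 HU), so a large
consolidated fraction makes TLV under-represent the anatomic lung and
decouples FLV/TLV from 1 − (non-functional fraction); with the mild default
the two agree to well under 2%.

Ground truth comes from the generative labels (which class each voxel was
drawn as), never from thresholding, so it is an independent oracle for the
segmentation stage. The small residual gap between, say, TLV and the true
lung volume is the Gaussian tail of the parenchyma distribution falling
outside the window — about 0.3% at the default SD of 50 HU.

Not emulated: airway trees beyond the trachea, vasculature, respiratory
motion, partial-volume blur, correlated CT noise texture, and real fissure
geometry. Passing phantom tests therefore demonstrates the correctness of
the volumetric arithmetic and the threshold/connectivity logic, not
robustness to the texture and artifacts of clinical scans.

## The cohort simulator

`simulate_cohort()` draws, per patient: preoperative FVC ~ N(2.92, 0.59) L
and FEV1 ~ N(2.41, 0.56) L, truncated above 0.5 L (the plain Normals would
occasionally produce impossible values); a surgical group
(lobectomy/segmentectomy/wedge, default mix 50/25/25%); a resected lobe
(weights following typical resection frequencies, upper lobes commonest);
and a loss ratio built from per-lobe FLV shares of total FLV (RUL 20.39,
RML 9.74, RLL 23.91, LUL 24.08, LLL 21.88%). A lobectomy loses the whole
share; a segmentectomy the share divided by the lobe's segment count; a
wedge 30% of the share — the scaling is this package's refinement so that
sublobar rows are physiologically smaller losses. Gaussian noise
(SD 0.03) is added and the ratio clipped to [0.01, 0.6]. Postoperative
values then follow the fixed linear equations plus Gaussian residuals with
the stated residual SDs, so with all noise set to zero the linear forms hold
exactly — the simulator and the predictor are the same model, which is what
makes parameter-recovery a meaningful end-to-end test.

For regression-recovery studies `delta_dist = "uniform"` replaces the
lobar draw with Δ ~ U(0.08, 0.30), giving the design spread that makes the
slope on Δ well identified. The per-lobe mean volumes printed in clinical
tables do not sum to the whole-lung means (they are means of per-patient
ratios), so the simulator trusts the percentage shares and does not try to
reconcile the millilitre column.

Reproducibility: one global seed, hashed into a named sub-stream per stage
(`phantom`, `cohort`), so adding draws to one stage never perturbs another,
and identical seeds give bit-identical outputs — the pipeline test asserts
byte-identical CSV/JSON across runs.

## The statistics battery

* **Pearson r** with the t-transform p-value on n − 2 df (via
  `stats::cor.test`).
* **ICC(A,1)** — two-way, absolute agreement, single measure — computed
  from mean squares. The absolute-agreement form is fixed deliberately: a
  prediction method that is systematically offset should be penalised, and
  the model choice is recorded in every report.
* **Bland–Altman** with differences oriented predicted − measured (a
  negative mean difference = underestimation) and limits at exactly
  ±1.96 SD (n − 1 denominator), not a t-quantile — the conventional plot
  multiplier.
* **OLS** (`ols_fit()`) wraps `stats::lm` and reports coefficients, 95%
  t-based CIs, two-sided p-values, R², residual SD √(SSE/(n−p−1)) and n.
* **Stepwise** (`stepwise_select()`) is forward selection with a backward
  check on partial t-test p-values, entry 0.05 / removal 0.10 (the classic
  SPSS convention), ties broken by smaller p then lexical name, so it is
  deterministic given the data. `stats::step` is AIC-based and therefore not
  a substitute. A caution that the suite quantifies: with several null
  candidates the family-wise false-entry rate at p_enter = 0.05 is
  1 − 0.95^k per step (≈ 30% with k = 7), so stepwise at conventional
  thresholds frequently admits one noise covariate alongside the true
  predictors. This is a property of the procedure, not an implementation
  artifact; tighten `p_enter` to about α/k when exact support recovery
  matters.
* **ANOVA across measured/SC/FLV** treats the three series as independent
  groups, matching common surgical-series reporting; strictly they are
  repeated measures on the same patients, and the report says so. No
  multiple-testing correction is applied anywhere, mirroring the p < 0.05
  convention of the source analyses.

## Problem sizes

The test suite and the acceptance script are sized for a single CPU:
parameter recovery at n = 5,000 (slope standard errors ≈ 0.008, so the
recovery band is tight), moment checks at n = 10,000, the stepwise
replicate study at 100 × n = 2,000 (at n = 500 the Δ slope's |t| ≈ 3.3 and
the *signal* itself fails to enter in ~9% of replicates; 2,000 removes that
power artifact so the study isolates the selection behaviour), and the
full-resolution phantom at 1 mm isotropic / 192×128×192 with a 2 mm
reduced-resolution twin for routine tests.

## Known limitations

* Pure-threshold TLV excludes atelectasis, fibrosis and tumour
  automatically (they sit above −500 HU), but partially aerated atelectasis
  is genuinely ambiguous; clinical workflows resolve it manually, this
  package does not.
* Only the tracheal column is removed, not the intrapulmonary bronchial
  tree; intrapulmonary airway air inside the TLV window therefore counts
  toward TLV.
* Segment counting is implemented in its uncorrected form (no exclusion of
  obstructed segments).
* No DICOM reader is shipped; convert series to NIfTI upstream.
* The simulator's agreement statistics cannot reproduce any particular
  clinical cohort's correlations — they validate the machinery, not the
  epidemiology.
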