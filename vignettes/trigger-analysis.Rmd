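---
title: "Trigger analysis for daily online adaptive radiotherapy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trigger analysis for daily online adaptive radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arttrigger)
```

## The problem

Online adaptive radiotherapy (ART) re-optimizes a treatment plan on the
anatomy of the day, during the treatment session. In the pelvis, anatomic
variation is dominated by day-to-day bladder and rectal filling: large,
random, and interfractional, so adaptation is best done *as needed* rather
than on a schedule. But adaptation is expensive in time and personnel, which
raises the operational question this package addresses: **at what observed
dosimetric change should a clinic adapt?**

The framework works with three dose distributions available at every
fraction:

* **Reference (REF)** — the original plan on the planning anatomy; fixed for
  the whole course.
* **Scheduled (SCH)** — the original plan recalculated on the daily anatomy;
  what would be delivered without adaptation.
* **Adapted (ADP)** — a plan re-optimized on the daily anatomy.

For each of 16 standardized dose metrics the three pairwise differences
SCH−REF, ADP−REF and ADP−SCH are computed per fraction. A *trigger* is a
parameter–value pair: a monitored difference (e.g. the SCH−REF change in PTV
D95%) and an action level. For every candidate value the framework computes

1. the **proportion of treatments adapted** — a fraction counts as adapted
   when the trigger fires *and* the adapted dose is preferred over the
   scheduled dose for that metric; and
2. the **counterfactual distribution** of the metric: ADP−REF values where
   adaptation occurred, SCH−REF values elsewhere, summarized by the 5/10/25/
   50/75/90/95th percentiles.

Because the preference condition is fixed per fraction, the
proportion-adapted curve is exactly the empirical CDF (taken in the
strictness direction) of the trigger parameter restricted to
preference-satisfying fractions, scaled by the preference-satisfying share.
This identity is what the test suite checks the sweep implementation
against, and it explains two qualitative features: the curve is monotone in
strictness, and it saturates below 100%.

## Dose-volume machinery

Metrics are read off the cumulative dose-volume histogram (DVH) of each
structure. Conventions, all chosen for exact reproducibility against a
brute-force voxel oracle:

* **Binary masks, voxel-centre convention.** A voxel is wholly in or out of
  a structure; no partial-volume weighting. Structure volume is voxel count
  × voxel volume, exactly.
* **Step-function quantiles on the voxel multiset.** Dx% / Dxcc return the
  largest DVH bin edge whose exceedance volume still covers the requested
  volume — the minimum dose of the hottest x% (or x cc), with no
  interpolation between voxel doses. VxGy returns the exceedance fraction at
  the smallest bin edge at or above the threshold; the curve's stated
  resolution is therefore one bin width, and volume queries are exact when
  the threshold lies on the bin lattice.
* **Bin width 0.01 Gy** by default, finer than any difference the summaries
  report (two decimal places).
* Grids are (z, y, x)-ordered arrays with per-axis spacing in mm. Empty
  masks and non-congruent grid/mask pairs are errors, never silent results.

Commercial planning systems use their own undocumented DVH interpolation;
numeric parity with any particular vendor is explicitly not attempted.

## The metric catalog

Sixteen metric slots per site: PTV D99%, D95%, D0.03cc; CTV D99%, V100%,
D0.03cc; bowel D2cc, V55Gy, D0.03cc; bladder V65Gy, V40Gy, D0.03cc; rectum
V65Gy, V40Gy, D0.03cc; and one combined femoral-heads D0.03cc slot evaluated
on the union of the left and right masks (the two femora are clinically
reported as one row, and one slot keeps the catalog at 16).

All analyzed dose distributions are single-fraction doses, so the catalog
works on the per-fraction scale throughout: V-metrics with absolute course
limits (V55Gy, V65Gy, V40Gy) scale the limit by the number of fractions
(e.g. 40 Gy over 20 fractions → 2.0 Gy per treatment), and Vx% thresholds
are x% of the per-fraction prescription.

Metric applicability is a function of site. For the hypofractionated bladder
group the bladder is the target, so its OAR constraints are
`not_appropriate`, and rectum V65Gy exceeds what a 55 Gy course can deliver
(`inadequate_dose`). The two remaining regimens' statuses are not published;
this package derives them from the same dose arithmetic: all slots valid for
the 70.2 Gy prostate + seminal-vesicles regimen, and V55/V65 limits
`inadequate_dose` for the 40 Gy SBRT regimen. Non-valid slots travel through
every table as status-only rows and are excluded from differences and
triggers — from numerator *and* denominator.

Metric direction is `higher_better` for the four coverage metrics (PTV
D99%/D95%, CTV D99%/V100%) and `lower_better` for everything else. The
target hot-spot (D0.03cc) direction is not discussed in the clinical
analyses this mirrors; treating a hotter target maximum as worse is the
conventional choice and can be overridden per policy via the `direction`
argument of `trigger_policy()`.

## Trigger semantics and numerical choices

* **Inclusive comparison**: a difference exactly equal to the action level
  fires. This makes the CDF identity exact rather than approximate.
* **Preference ties**: `adp_sch` exactly 0 is *not* preferred — adapting
  buys nothing dosimetrically. Configurable in principle by the caller
  (adapt the decision table), but the default is deliberate.
* **Default value grids**: `floor(min)` to `ceiling(max)` of the observed
  differences, step 0.25 Gy for dose metrics and 1 percentage point for
  volume metrics. Integer-only grids are too coarse to resolve the
  0.25/0.5 Gy action levels that matter in practice for per-fraction dose
  metrics. When an observed extreme lands exactly on a grid point the grid
  is extended by one step so its laxest end provably fires nothing — this
  also gives degenerate all-zero difference metrics a well-defined sweep.
* **Quantiles everywhere** (medians, IQRs, percentile bands) use linear
  interpolation between closest ranks (R type 7); IQR = Q3 − Q1 under the
  same convention.
* Summaries pool fractions across patients within a site by default,
  matching how the cohort-level analyses are read; `per_patient = TRUE`
  collapses to patient medians first for sensitivity checks.

## The synthetic cohort generator

Clinical per-fraction dose data of this kind are not publicly shared, so the
package ships a generator that emulates the *statistical structure* the
analysis relies on, at the clinical cohort scale (4/2/8/2 patients at
20/11/26/5 fractions per site = 320 fractions):

* **Reference values** are drawn once per patient and held constant across
  fractions.
* **SCH−REF** differences follow a skew-normal: left-skewed for coverage
  metrics (anatomic change mostly erodes coverage, occasionally improves
  it), right-skewed or symmetric for OAR metrics. Shape `alpha = −4` for
  coverage and `+2` for skewed OAR presets; location and scale are solved
  *exactly* from the target median and IQR via the skew-normal quantile
  function (`calibrate_skewnorm()`).
* **Interpatient variation** is a patient-level random intercept. Half of
  the symmetric scale component of the calibrated skew-normal is assigned to
  the intercept and the remainder to fraction noise; by normal convolution
  closure the *marginal* SCH−REF distribution stays exactly the calibrated
  skew-normal, so parameter-recovery tolerances can be computed analytically
  (asymptotic quantile standard errors from the known density) instead of
  being tuned.
* **ADP−REF** differences are tight zero-ish normals — the adapted plan
  tracks the reference.
* **Preference violations** (fractions where the adapted dose is no better
  than the scheduled one) are not injected separately: they arise from the
  overlap of the SCH and ADP noise distributions, e.g. days when anatomy
  drifted the target into a *higher*-dose region. This is what caps the
  proportion-adapted curve below 100%.
* **Stream discipline**: each patient's values come from a substream derived
  from the master seed and the patient's index, so enlarging a site's
  enrolment never perturbs already-generated patients.

Calibration targets for the hypofractionated-bladder and fossa-boost groups
are the published per-metric medians/IQRs; the prostate + seminal-vesicles
PTV D95% row uses the published −0.14 Gy / 0.28 Gy. Remaining rows
(most of the prostate + seminal-vesicles group, all of SBRT) are synthetic
defaults consistent with the published cross-site ranges and are labelled as
such in `default_metric_params()`.

What the generator does **not** emulate: correlation between metrics within
a fraction (each metric is drawn independently), serial correlation across a
patient's fractions beyond the random intercept, bounded supports (a V-metric
difference is not clipped to keep the absolute value within 0–100%), and any
mechanistic link between anatomy and dose. Passing tests on this cohort
therefore validate the *analysis machinery* — identities, conventions,
monotonicity, calibration recovery — not clinical effect sizes.

## The voxel phantom

`phantom_spec()` builds a geometric caricature: a spherical CTV expanded by
a 3–5 mm margin to the PTV, spherical OAR stand-ins (rectum posterior,
bladder anterior, bowel superior, femora lateral), per-fraction prescription
dose uniform in the PTV with a Gaussian penumbra (default SD 4 mm), and
daily anatomy modelled as one rigid displacement (default per-axis SD 3 mm)
of all structures. The adapted dose is the reference dose field rigidly
re-centred on the displaced target — no optimizer. This is the simplest
mechanism that reproduces the compromise/recovery signature: zero
displacement leaves SCH ≡ REF; displacement well beyond the margin pulls
PTV D95%/D99% down in the scheduled dose while the adapted dose stays at the
reference value; displacement within the margin leaves CTV coverage intact.
Default grid 30³ voxels at 2 mm spacing keeps a full course of evaluations
in seconds. It is not an anatomy model: no deformation, no filling
mechanics, no reoptimization trade-offs.

## Problem sizes used in tests and the acceptance script

DVH oracle checks use 200 random grids up to 20³ voxels; identity and
parameter-recovery checks use a 5 200-fraction single-site cohort (200
patients × 26 fractions); sweep-oracle checks cover every valid site ×
metric × contrast of the 320-fraction cohort; phantom checks use single
fractions at 30³ voxels. These sizes make every distributional check
comfortably larger than its Monte-Carlo error while keeping the whole suite
at desk scale.

## Known limitations

* Dose accumulation across fractions is out of scope by design; every
  fraction is judged within the scope of its own adaptive intervention.
* One trigger, one metric: multi-metric triggers with logical combinations,
  and cross-metric effects of a single trigger, are future work.
* Descriptive statistics only; no inferential claims are made about the
  synthetic cohorts, and synthetic calibration values for the unpublished
  site/metric combinations should not be quoted as clinical results.
* The DVH engine targets reproducibility, not parity with any treatment
  planning system's proprietary binning.
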