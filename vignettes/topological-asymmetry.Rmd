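---
title: "Topological analysis of hemispheric asymmetry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological analysis of hemispheric asymmetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asymtopo)
```

## The measurement problem

Deformation-based asymmetry imaging warps each brain to a left-right
symmetrical template and records, per voxel, the log volumetric expansion or
contraction needed. Subtracting each voxel's homologous (mirrored) value
(`flip_subtract()`) produces an exactly antisymmetric volume in which bright
(hyperintense) voxels mark structures that are larger on that side than their
contralateral homologue.

A bright asymmetric structure is a *2-cycle* of the sublevel-set filtration
of this volume: as voxels are introduced from dark to bright, a cavity forms
when the structure's surroundings are all present but its interior is not.
The cavity's **birth** is the enclosing boundary level of the structure and
its **death** is the structure's peak asymmetry value; the difference is the
structure's magnitude. This measurement deliberately summarises the *maximum*
asymmetry originating within a region — a voxel-averaging baseline
(`roi_mean_asymmetry()`) is also provided, and behaves differently because
averages are diluted by the surrounding symmetric tissue and contaminated by
structures originating outside the region.

## Cubical persistence: conventions

`sublevel_2cycles()` computes all finite degree-2 pairs of a 3D volume.
Numerical conventions, all configurable or documented here because different
imaging packages make different choices:

* **Cell construction.** Voxels are vertices of the cubical complex and every
  square and cube takes the maximum value of its vertices. Equivalently, the
  dark (sublevel) phase is 6-connected and the bright phase 26-connected.
* **Boundary handling.** The image is a solid block with no padding: a bright
  structure must be enclosed by in-image voxels to count as a cavity. A
  bright region touching the image boundary is connected to the outside and
  never encloses a cavity.
* **Tie-breaking.** Voxels with equal values are processed in lexicographic
  order; the `peak_voxel` of a pair is the voxel attaining the death value
  within the dying component, ties broken by smallest lexicographic index.
  The (birth, death) multiset itself does not depend on tie order.
* **Zero-persistence pairs are dropped**, and `death_min` can act as a noise
  floor.

Two independent routes are implemented: a merge-tree scan of superlevel-set
components (C++, default; a virtual "outside" node with peak `+Inf`
implements the boundary convention, and components die by the elder rule) and
a direct GF(2) boundary-matrix reduction of the sublevel complex
(`method = "reduction"`). The test suite checks the two routes against each
other and against a third, independently coded dense reduction oracle on
hundreds of tie-heavy random integer volumes, plus hand-derived analytic
cases (single enclosed peak, two peaks joined by a ridge, monotone ramps,
constants).

Pairs are assigned to atlas regions by the location of their **peak voxel
only** (`assign_pairs()`): persistence is computed on the whole volume, never
on masked subvolumes, because masking would alter births at region borders.
A pair whose spatial extent straddles several regions is therefore counted
exactly once.

## Landscapes on a fixed position grid

The first persistence landscape
\[
\lambda(t) = \max_{(b, d)} \max\{0, \min(t - b,\; d - t)\}
\]
is the magnitude of the most asymmetric structure whose span covers boundary
level \(t\). It is sampled on `G = 15` equally spaced positions
(`landscape_grid()`), with the grid bounds taken from the *pooled* diagrams
of a sample (minimum birth to maximum death) so every participant is sampled
at the same positions. Pooling is per scope family: all left-hemisphere
scopes share one grid and all right-hemisphere scopes another; whether to
pool across hemispheres instead is exposed by passing a common grid. The
endpoint positions are exactly zero by construction, so analyses use the 13
interior positions (`build_matrix()`).

The landscape obeys, and the tests assert: non-negativity, 1-Lipschitz
continuity in \(t\), invariance to dominated pairs, monotonicity under pair
insertion, the bound \(\lambda \le (hi - lo)/2\), and the identity that a
hemisphere's landscape is the pointwise maximum of its regions' landscapes.

## The two hypotheses and their models

**Cerebral lateralization** predicts a *linear* association between asymmetry
magnitude and a standardized behavioral score (phonological decoding, mean
100, sd 15). Decoding is first residualized on age, sex and research site
(`residualize()`; site categorical), then regressed on the landscape value at
each position (`fit_linear()`). The printed degrees of freedom in the source
analyses equal \(n - 2\), which identifies this residualize-then-fit
convention rather than a joint multiple regression; we follow it. Effect
sizes use \(d = 2t/\sqrt{df}\) (`cohen_d_from_t()`), which reproduces the
pediatric conversion (t = 3.40, df = 420 gives d = 0.332) but not the adult
one (t = 3.91, df = 297 would give 0.454, not the reported 0.382); the
original convention for that value is not stated, so we document the
discrepancy rather than reconcile it silently.

**Canalization** predicts a sandpile geometry: the most asymmetric
individuals cluster at *average* behavior, so the upper envelope of asymmetry
as a function of behavior is an inverted U. `fit_quantile_sandpile()` fits
the 99th conditional percentile (tau = 0.99) of the landscape value on an
orthonormal degree-2 polynomial basis of residualized decoding (`poly()`,
centered Gram-Schmidt), minimizing the check loss
\(\sum_i \rho_\tau(a_i - X_i\beta)\); a negative quadratic coefficient is the
canalization signature. The solve uses the exact Barrodale-Roberts simplex
(`quantreg::rq.fit.br`); tests verify the coefficients against an exhaustive
basic-solution enumeration oracle to 1e-6 on small data sets. Because ROI
landscape values contain many exact zeros, a uniform jitter of at most 1e-5
(`jitter_values()`) is added to the landscape vector — drawn *once per
analysis*, not per bootstrap draw, so resampling stays conditional on one
fixed data set; the jitter is orders of magnitude below any effect of
interest.

Hemisphere-aggregate landscape data are approximately normal and use the
linear model by default; single-ROI landscape data are strongly left-skewed
and use the quantile model; both models are selectable for any scope.

## Uncertainty: imputation, bootstrap, pooling

Behavioral scores may be missing. `chained_imputation()` implements chained
equations with predictive-mean matching (10 cycles, 5 donors): each
incomplete column is regressed on all others, and every missing cell receives
an *observed* value from a nearest-predicted-value donor, giving `m`
completed tables (default 10). `bootstrap_pool()` draws `B` participant
resamples with replacement per imputation (desk default 1000; full-scale
10000) and `pool_over_imputations()` averages all `m x B` fits per position.
Two p-values are reported, because the original pooling rule is not stated:
`p_pooled_t` from the pooled t statistic with df = n - 2 (default for the
linear model), and `p_bootstrap`, the doubled fraction of draws crossing zero
floored at 1/B (default for the quantile model, which has no usable
asymptotic theory at tau = 0.99).

Participants whose decoding score equals a listed outlier value exactly
(`exclude_outliers()`) are removed before analysis, mirroring the documented
exclusion of specific standard scores.

## Family-wise error and replication

Adjacent landscape positions are highly correlated, so position-wise
`alpha < 0.05` calls (strict inequality; `threshold_mask()`, split by
estimate sign) are corrected by a run-length extent rule: `extent_null()`
resamples significance indicators i.i.d. with replacement (10,000 times) and
records the maximum run of adjacent significant positions; the cutoff `k*`
is the smallest run length with null probability below 0.05, and
`apply_extent()` keeps only observed runs of at least `k*`. We read
"reordered with replacement" as i.i.d. indicator resampling — a bootstrap of
position labels — and build the null separately per direction. The cutoff is
exact against enumeration on small masks in the tests.

Which indicators feed the resampler matters. Resampling each landscape's
*own* indicators (`extent_pool = "scope"`) makes the cutoff scale with that
landscape's significance density, and is self-defeating for a genuine
effect: if the mask is a single contiguous run of length T out of L, the
resampled chance of a T-run at density T/L stays above 5% for every T, so
the observed run can never survive its own null. The pipeline therefore
defaults to `extent_pool = "family"`: the run-length null is estimated from
the indicators counted across *all* analyzed landscapes of the cohort and
direction, so the mostly-null landscapes set the chance level — this is also
the natural reading of determining one 95% cutoff after counting results
across landscapes. The family-wise error of the full procedure under the
global null is verified by simulation either way.

Finally `replication_gate()` declares an effect significant only when it
survives extent correction in *both* samples at the same position and
direction; `run_pipeline()` orchestrates the whole sequence per cohort and
reports single-sample and replicated effects separately.

## The synthetic cohort generator

`simulate_cohort()` provides ground truth for every stage. Design choices,
fixed once:

* **Geometry.** Default volumes are 12x12x12 with the flip axis first (even
  length, so antisymmetry is exact and no voxel maps to itself); 8 box ROIs
  per hemisphere, mirrored so homologous labels correspond. ROI boxes are
  never split along the flip axis and a 1-voxel background margin is kept,
  so blob interiors stay away from the midline and the image faces.
* **Structures.** One Gaussian blob per hemisphere (sd 0.8 voxels), centered
  in a uniformly drawn ROI with 1-voxel placement jitter, kept at least two
  voxels from every image face and from the midline, and the right ROI is
  chosen with its mirrored box separated from the left ROI's box: mirrored
  overlapping structures would cancel under flip-subtraction and make the
  per-hemisphere ground truth ambiguous. Blob amplitudes are uniform on
  [1, 2]: bounded away from zero so each participant carries one
  well-defined structure, and within a factor of two so the landscape at
  mid-grid positions responds linearly to amplitude.
* **Noise.** Jacobian background noise is i.i.d. Gaussian, sd 0.02 (the
  asymmetry image noise is sqrt(2) larger). This produces a realistic carpet
  of low-persistence pairs (births and deaths near zero) under the tall blob
  pairs without obscuring them; the voxel-value distribution of real
  asymmetry images is not published, so this level is a free parameter of
  the generator, not a calibrated one. Gaussian pre-smoothing of the
  Jacobian is available (`smooth_sigma`, and on by default in
  `asymmetry_from_jacobian()`) but defaults to off here because the blobs
  are already smooth.
* **Couplings.** `null`: decoding independent of amplitude. `linear`:
  decoding = 100 + 15(r z + sqrt(1 - r^2) e) with z the
  population-standardized left amplitude, giving population correlation
  exactly `target_r`. `canalized`: decoding is drawn first and the left
  amplitude is `strength * max(0, 1 - ((decoding - 100)/30)^2) * u` with u
  uniform on (0, 1): the envelope spans +/-2 sd of the score scale (width
  30), peaks at average performance, and `strength` (default 2, matching
  the upper end of the linear amplitude range) sets its height. Covariate
  effects on decoding default to zero so recovery tests isolate the
  coupling; they are configurable. Missingness is MCAR on the behavioral
  columns only.

Everything is reproducible bit-for-bit from the cohort seed.

What the generator does *not* emulate: registration error, site-dependent
image contrast, cortical folding geometry, or spatially structured noise.
Passing recovery tests therefore demonstrate that the statistical machinery
detects the intended couplings through the full topological measurement
chain — not that real asymmetry images carry such signals.

## Simulation scales used by the test suite

The package's property and calibration tests run at sizes chosen to make the
Monte-Carlo error small relative to the asserted margins: null calibration
uses 100 pipeline runs of two n = 200 cohorts (B = 200, m = 2), confirming a
replication-gated family-wise error at or below 6% and per-position
uncorrected rejection rates inside [0.03, 0.08]; linear recovery uses 200
cohorts of n = 400 at population r = 0.16 (the effect scale implied by
t = 3.40 at df = 420), confirming power of at least 0.80 at the informative
position; canalization recovery uses 100 cohorts of n = 700, confirming a
negative pooled quadratic coefficient in at least 90% of replicates and a
near-alpha signed rejection rate under the null.

## Known limitations

* Only the first landscape (the maximum) is computed; deeper landscape
  functions carry information about secondary structures that this analysis
  deliberately ignores.
* Grids are frozen per sample, so replication compares position *indices*,
  not identical asymmetry values, across samples — the same convention as
  the position-wise replication rule it implements.
* The extent correction treats positions as exchangeable under the null;
  its calibration under strong long-range dependence is checked empirically
  (criterion-level simulations), not analytically.
* Degree-0 and degree-1 features (components, tunnels), persistence images
  and kernel embeddings are out of scope.
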