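---
title: "From tensor fields to treatment effects: the svdnet methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From tensor fields to treatment effects: the svdnet methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svdnet)
```

# Overview

`svdnet` implements a complete diffusion-tensor network analysis for
longitudinal trials in cerebral small vessel disease (SVD): synthetic
tensor-field phantoms and simulated two-arm cohorts, diffusion tensor
fitting with fractional anisotropy (FA) and mean diffusivity (MD)
histogram metrics, deterministic streamline tractography, construction of
inverse-length-weighted structural connectomes over a labelled
parcellation, weighted global and local network efficiency, and a
permutational repeated-measures ANCOVA for the group-by-time treatment
effect. This vignette explains the models behind each stage, the
parameters that matter, and the design decisions taken where the
methodology left genuine choices open.

Real trial MRI data of this kind is not publicly deposited, so every
stage here is exercised end-to-end on synthetic inputs whose ground truth
is known by construction. The phantom and cohort generators are
first-class, tested components, not test scaffolding.

# Synthetic phantoms

`make_bundle_phantom()` builds a voxel grid of symmetric 3x3 diffusion
tensors (stored as the 6 unique components, units mm²/s) containing one
or more coherent fiber bundles: tubes of configurable radius around a
polyline centerline. Voxels inside a tube receive a tensor whose
principal eigenvector follows the local centerline tangent with
eigenvalues such as (1.7, 0.2, 0.2)x10⁻³ mm²/s — the classic prolate
white-matter profile with FA 0.870; all other voxels receive an isotropic
background (FA = 0). Spherical caps at the two centerline endpoints are
painted with integer parcellation labels so that streamlines following
the bundle terminate inside labelled regions, which guarantees that the
connectome stage always has a well-defined ground-truth edge. The
white-matter mask is the set of voxels whose FA exceeds the background's
(equivalently, the in-bundle voxels).

`simulate_dwi()` produces diffusion-weighted signals from the
monoexponential tensor model `S = S0 exp(-b gᵀDg)` for an arbitrary
gradient table; `gradient_scheme()` supplies an approximately uniform
32-direction, b = 1000 s/mm² scheme (Fibonacci spiral) emulating the
acquisition such trials use. Noise, when requested, is Rician — two
independent Gaussian channels combined as a magnitude — because that is
the physics of magnitude MRI; `noise_sd = 0` recovers the exact model, so
the tensor-fit round trip can be tested to numerical precision.

What the phantoms deliberately do not model: crossing fibers, partial
volume beyond trilinear blending at tube boundaries, scanner-specific
artifacts, or multi-shell acquisitions. Passing tests on these phantoms
therefore demonstrates the correctness of the numerics — interpolation,
integration, termination rules, edge accounting, inference — not
robustness to the full messiness of in-vivo data.

# Tensor fitting and histogram metrics

`tensor_fit()` solves the log-linear least-squares problem
`log S = log S0 - b gᵀDg` per voxel, the standard first-pass DTI fit. A
weighted refinement is intentionally not applied: the plain OLS fit is
the simplest model consistent with the pipeline description, and on
noise-free phantoms it is exact, which the round-trip tests exploit.
Voxels with non-positive signals (possible under extreme noise) are
flagged invalid and excluded rather than silently log-transformed.

FA and MD come from the eigenvalues via closed forms (`fa_map()` uses the
analytic symmetric-3x3 eigenvalue solution, vectorized over voxels).
Negative eigenvalues — a known artifact of linear fitting under noise —
are clamped to zero before FA and the affected voxel count is reported.

`histogram_summary()` implements the white-matter histogram convention
used in SVD trials: normalized histograms with 1,000 bins over FA range
0-1 (bin width 0.001) or MD range 0-4x10⁻³ mm²/s (bin width 0.004x10⁻³),
from which the peak height, peak location and median are extracted.
Numerical choices, all deterministic:

* bins are right-open `[k·w, (k+1)·w)`; a value sitting on a bin edge up
  to representation error is assigned to the upper bin;
* ties for the peak break toward the lowest bin index;
* the peak location is reported at the bin *center* (edge vs center is
  not dictated by convention; the center is the symmetric choice);
* the median is computed from the raw masked voxel values, not from the
  binned counts — more precise, and testable against a sort oracle;
* out-of-range values are clipped into the terminal bins (preserving
  normalization) and counted.

`wmh_lesion_load()` is the white-matter-hyperintensity burden score:
lesion volume as a percentage of whole-brain volume. The cohort
simulator's defaults center it at 3.4% with SD 2.3, the severe-SVD range.

# Deterministic tractography

`whole_brain_tractography()` integrates streamlines through the principal
eigenvector field of the tensor volume. Defaults follow the
tensor-deterministic configuration used in SVD network studies: step size
0.5 mm; maximum turning angle between successive steps 45°; track length
window 20-250 mm; FA termination cutoff 0.15; 4th-order Runge-Kutta
integration; and seeding on an evenly spaced sub-voxel grid with 4
subdivisions per axis (0.5 mm spacing at 2 mm voxels). "Grid size 4" and
"0.5 mm³ super-resolution seeding" are mutually consistent only under
that reading, which is the one implemented; seeds sit at sub-cell
centers.

Details that matter for correctness:

* the tensor is interpolated component-wise (trilinear) — this preserves
  symmetry, and the direction is the principal eigenvector of the
  *interpolated* tensor;
* eigenvector fields are axial (±v are the same physical direction), so
  every RK4 stage direction is re-sign-aligned with the incoming
  direction; without this, stages can cancel and corrupt the integral;
* the turning-angle check applies between successive step displacement
  vectors, matching "angle between successive steps";
* FA is checked at the candidate next point *before* it is appended, so
  every stored point lies in the FA ≥ cutoff region;
* propagation is bidirectional from the seed; a seed whose both branches
  terminate immediately is rejected as degenerate;
* tracks longer than the maximum are discarded by default ("maximum
  length of any track" read as an acceptance bound); a `truncate` switch
  is provided;
* there is no randomness anywhere: a tractogram is a pure function of
  tensors, mask and parameters, and reruns are bit-identical.

On a constant field RK4 is exact, so straight-bundle phantoms yield
exactly straight streamlines — the geometry tests assert deviations below
10⁻⁶ mm, and track lengths against a closed-form oracle for where the
interpolated FA crosses the cutoff. The inner loop is implemented in
C++ (Rcpp/RcppArmadillo), as is usual for tractography.

One caveat worth knowing: with trilinear interpolation an idealized sharp
bend in the field is smeared over one voxel. If the voxel size approaches
the step size, a 60° bend can be traversed as two sub-45° turns. The
bend-termination tests therefore build the discontinuity at fine voxel
size relative to the 0.5 mm step, where the angle criterion acts as
intended.

# Connectome construction

`build_connectome()` maps each accepted streamline to the parcellation
labels of the voxels containing its two terminal points (nearest-voxel
assignment; no dilation or radial search — the simplest reading of
"terminating in region A"). Streamlines with an unlabeled endpoint are
dropped, and streamlines terminating in their region of origin are
removed. Each remaining streamline contributes `1/length` (mm⁻¹) to its
edge: under super-resolution seeding a long pathway accumulates
proportionally more seeds, and the inverse-length weight compensates
exactly for that multiplicity. The result is symmetric with a zero
diagonal, and total weight equals the streamline-level sum — a
conservation law the tests check against an independent loop.

No normalization by region volume or total streamline count is applied;
whether the original analyses did so is not recoverable, and adding one
would change only the overall scale of the efficiency metrics, not the
inference.

# Weighted efficiency metrics

Distances on the connectome are reciprocal weights (`d = 1/w`), the
standard mapping for connection-strength matrices. Then:

* **global efficiency** `E_glob = (1/(N(N-1))) Σ_{i≠j} 1/d(i,j)` with
  `1/∞ = 0` — unreachable pairs contribute zero rather than being dropped,
  which preserves the `N(N-1)` normalization and penalizes fragmentation;
* **local efficiency** is the mean over all nodes of the global
  efficiency of each node's neighbor-induced subgraph with the original
  weights (the Latora-Marchiori form); nodes with fewer than two
  neighbors contribute 0.

The neighbor-subgraph form is the default because it matches the
plain-language meaning of local fault tolerance; the cube-root weighted
variant found in some toolboxes is available via
`local_efficiency(variant = "onnela")`. Published analyses rarely state
which variant their toolchain computed, so both are provided and the
default documented.

Shortest paths are delegated to igraph (Dijkstra); the test suite
cross-checks them against a hand-written Floyd-Warshall and, for all
connected graphs on up to 5 nodes, against exhaustive simple-path
enumeration. Useful invariants: scaling all weights by `c` scales
`E_glob` by exactly `c`; adding or strengthening an edge never decreases
it.

# Simulated cohorts

`simulate_cohort()` draws a two-arm (standard vs intensive), two-visit
(baseline, 2-year follow-up) cohort: by default 40 + 42 subjects over 6
sites, matching the structure of the trial setting this pipeline
addresses. The metric model is

```
metric_st = baseline_mean + site_s + subject_s + slope_arm · t + ε_st
```

with `t ∈ {0, 1}` (per 2 years), site effects `N(0, site_sd)` drawn once
per site, a per-subject intercept composed of two independent Gaussian
components (`baseline_sd` for stable between-subject heterogeneity,
`subject_sd` for an additional random intercept — they add in
quadrature), and i.i.d. residuals. Subjects are assigned to sites
round-robin within each arm: deterministic, balanced, and reproducible.
WMH lesion load is Gaussian at baseline (mean 3.4%, SD 2.3) with a
Gaussian 2-year increment, both truncated at zero. Adherence flags are
Bernoulli with arm-specific probabilities defaulting to 35/40 and 28/42
— the per-protocol pattern of the emulating trial. All randomness flows
from the single integer seed in the spec.

Scale defaults for the metric itself (baseline 0.70, residual SD 0.025)
are chosen to resemble weighted global efficiency values on
inverse-length connectomes at trial-plausible noise; no public table pins
these, so they are package defaults, documented here, and every
calibration result in the test suite is stated relative to them (e.g.
effects in units of the residual SD).

# Permutational repeated-measures ANCOVA

With exactly two time points, the repeated-measures decomposition reduces
*exactly* to per-subject summaries: writing `Δ_s` for each subject's
follow-up minus baseline and `m_s` for the subject mean,

* the **group-by-time interaction** F is the F for group in
  `Δ ~ group + site` — the treatment-effect test;
* the **group main effect** F is the F for group in `m ~ group + site`;
* the **time main effect** F is the intercept test in `Δ ~ 1 + site` with
  sum-coded site columns (the intercept is then the site-averaged mean
  change).

This Δ-reduction is the canonical implementation here because it is
algebraically equivalent to the full split-plot decomposition for two
time points (the suite verifies the equivalence against an independently
coded long-format model with subject dummies, to 10⁻⁸) and far easier to
permute correctly. Site enters as a fixed covariate (sum-coded), so a
constant shift at any one site leaves all three F statistics unchanged.

Inference is permutational throughout, because network metrics in
patient cohorts carry heavy-tailed outliers that break normal-theory
ANCOVA. The exchangeable unit is the *subject* — both time points move
together — and label shuffles are stratified by site by default, since
site is a fixed design factor, not an exchangeable one. For the time
effect the sign of each subject's Δ is flipped instead. p-values use the
add-one estimator `p = (1 + #{F* ≥ F_obs})/(1 + B)`, which is bounded
below by `1/(B+1)`, never zero, and counts ties as extreme
(conservative). Everything is bit-reproducible given the seed.

`wmh_adjusted_test()` re-tests the interaction with the baseline lesion
load (intercept) and its 2-year change (slope) as additional covariates,
to check that an apparent network effect is not merely SVD severity in
disguise. Covariate-adjusted permutation uses the Freedman-Lane scheme —
permute the residuals of the nuisance-only model, rebuild the outcome,
re-test — the standard small-sample-safe choice where no scheme is
otherwise dictated. Zero-variance covariates are dropped with a warning;
if none remain the function falls back to the unadjusted test exactly.

Degenerate inputs have defined answers: a constant metric gives F = 0 and
p = 1; a noise-free cohort with opposite arm slopes gives a zero residual
with a real effect, reported as `F = Inf` and flagged as perfect
separation. No multiple-testing correction is applied across metrics;
per-metric p-values are reported as is, which mirrors how such trials
report them and is noted here so users can correct externally if needed.

`per_protocol_subset()` restricts to adherent subjects (both visits
retained) and errors if a group empties — the guard for meaningless
contrasts.

## Calibration and power, as tested

The acceptance suite verifies, at the default trial geometry
(n = 40/42, 6 sites, B = 999):

* empirical type-I error of the interaction, group and time tests — and
  of the WMH-adjusted interaction test — within the exact binomial 99%
  interval around α = 0.05 over 1,000 simulated null cohorts;
* Monte-Carlo p within enumeration error of the exhaustive permutation
  distribution on small single-site cohorts;
* power monotone in the injected effect size, exceeding 50% when the
  arms diverge by 0.8 residual SD over two years — consistent in
  character with post hoc power in the high-50s-to-70s percent range
  reported for trials of this size.

Problem sizes in the suite (phantom grids of a few tens of voxels per
axis, 1,000-cohort calibrations, B = 999) are chosen so the full suite
runs on a laptop-class single core in a few minutes while keeping every
Monte-Carlo interval narrow enough to be informative.

# Pipeline orchestration

`run_pipeline()` chains phantom → DWI simulation → tensor refit → FA/MD
histograms → tractography → connectome → efficiency metrics → cohort
simulation → permutational analysis, from a single nested configuration
(R list or JSON). Every artifact is written to the output directory
(NIfTI volumes, TSV tables, a TCK tractogram with a TSV sidecar, JSON
statistics) and a manifest records parameters and MD5 checksums; reruns
with the same configuration are checksum-identical. A stage log with
wall times supports auditing. `svdnet_demo()` runs a bundled
two-bundle, 20-subject configuration in well under a minute. A thin
command-line wrapper (`inst/cli/svdnet`) exposes `run` and `demo`; the
exported per-stage functions are the API for everything else.

# Known limitations

* Two time points only: the Δ-reduction is exact there; longer designs
  would need the mixed-model machinery deliberately left out of scope.
* Analysis of covariance with baseline as covariate is not implemented;
  the repeated-measures formulation used here is generally the more
  powerful of the two for this design, which is why it is the one
  provided.
* Phantoms contain single-orientation bundles; crossing-fiber behavior
  of the tracker is untested and out of scope.
* The parcellation in real use has 90 regions; phantom parcellations
  have as many labels as bundle endpoints. Nothing in the connectome or
  metric code depends on the region count.
* Sharp-bend termination interacts with voxel size as described above.
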