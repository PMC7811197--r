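---
title: "Density-profile morphometry of bacterial cellulose ribbons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-profile morphometry of bacterial cellulose ribbons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribbonmetrics)
```

## The measurement problem

Cellulose-producing *Gluconacetobacter* cells extrude crystalline
microfibrils that coalesce into flat sheets; stacked sheets form the
ribbon that runs along one side of the cell. Electron cryotomograms of
such cells show, along a line drawn normal to the cell envelope, a
characteristic sequence of density peaks: cytoplasmic cortical-belt
layers, the inner membrane (IM), the outer membrane (OM), and one or
more extracellular cellulose sheets. The morphometry of this system —
how far the ribbon sits from the OM, how sheets are spaced, how wide
they are, how the cortical belt is layered — is read off *averaged,
normalized 1-D density profiles*: the density is sampled along an
annotated line, averaged over a small rectangle of parallel lines, and
min–max normalized; distances are then peak-to-peak separations of the
profile maxima, and widths/diameters are full widths at half maximum
(FWHM).

`ribbonmetrics` re-implements this metrology as a tested pipeline and
validates it by *parameter recovery*: synthetic tomographic phantoms are
rendered with known geometry, degraded with the imaging artifacts
characteristic of cryo-ET, measured with the same pipeline a real
tomogram would be, and the recovered quantities are compared with the
ground truth.

## The phantom generator

`phantom_spec()` describes planar layers (soft-edged slabs stacked along
the profile axis, optionally of finite transverse width) and cylinders
(microfibrils). `render_phantom()` renders them additively on a constant
background with an edge softness of one voxel and derives every
ground-truth distance implied by the layer offsets.

`canonical_ribbon_phantom()` fixes the study conditions used throughout
validation:

* grid 128 × 256 × 256 voxels (beam, profile, transverse) of 0.7 nm —
  enough to resolve 6–16 nm features with ≥ 8 voxels while keeping a
  full render-and-measure cycle in seconds;
* membranes 6 nm thick at amplitude 1.0, sheets 8 nm at 0.8,
  belt layers 6 nm at 0.7, background 0. Densities are positive peaks
  (bright = dense), matching how features appear in profile plots;
  inverting real cryo-ET contrast is the caller's responsibility at
  import. The relative amplitudes are conventions — tomographic contrast
  between these structures is not quantitatively known — and are echoed
  into the ground-truth sidecar;
* an IM–OM separation of 30 nm, a typical Gram-negative periplasm;
  this value is recorded in the ground truth so nothing downstream
  depends on it implicitly;
* the `tight` variant places sheets 16 nm from the OM and 16 nm apart,
  and three belt layers 24 nm inside the IM spaced 15 nm; `loose`
  places a single sheet 99 nm out; `width` uses a 38 nm-wide sheet and
  a 47 nm-wide belt slab; `fibril` an 11 nm cylinder normal to the OM.
  These are the reported mean dimensions of the system the generator
  emulates, so recovery can be compared against them directly.

## The imaging model

Three operators emulate the dominant cryo-ET artifacts:

* **`apply_psf()`** — isotropic Gaussian blur with a physical sigma
  (default 2 nm), a proxy for defocus. Defocus in the source imaging
  protocol (−2 to −8 μm) matters here only qualitatively: it inflates
  apparent thicknesses. A Gaussian reproduces exactly that, so no CTF is
  simulated. The blur is a circular convolution with a sampled,
  sum-normalised separable kernel, which conserves total density
  exactly and equals the brute-force direct-space convolution the test
  suite checks against.
* **`apply_missing_wedge()`** — a hard binary Fourier mask zeroing the
  wedge of coefficients a ±`tilt_range` single-axis tilt series never
  samples (default ±60°). The beam axis is grid axis 1; the tilt axis is
  selectable. Point sources elongate along the beam by the classical
  factor `sqrt((a + sin a cos a)/(a − sin a cos a))` ≈ 1.55 at 60°,
  while distances along the tilt axis are untouched — both are tested
  properties, mirroring the two artifact claims that motivate
  measurement-line placement below.
* **`add_noise()`** — additive white Gaussian noise with an explicit
  seed; SNR is defined as strongest feature amplitude / noise SD, and
  the canonical SNR of 2 therefore means noise SD 0.5.

`apply_imaging()` composes them in acquisition order: noise first, then
the two Fourier filters. This mirrors the real data chain — noise
enters at the detector, and reconstruction applies low-pass/denoising
filtering to the noisy tilt series — so the blur stands for defocus
*and* for that reconstruction filtering. Composing the other way
(filtering the signal but leaving the noise white at full bandwidth)
models a reconstruction nobody performs, and its full-band noise
extremes on long profiles masquerade as density peaks. Each operator
keeps its individual contract (exact SD at injection, identity cases,
linearity), and `run_recovery()` exploits the linearity of the filters
to reuse the filtered signal across replicate noise draws — exactly
equivalent to imaging each replicate from scratch, at a fraction of the
cost.

## The profiler

`extract_profile()` samples the volume by trilinear interpolation at
half-voxel steps along the line, averages over a rectangle of parallel
lines (defaults 20 nm × 10 nm, the analogue of reading a profile off a
~10 nm-thick displayed slice; the original averaging dimensions are not
documented anywhere, so these defaults are conventions and are
configurable per line), and min–max normalizes. A constant profile is
returned flagged as degenerate at 0.5 rather than failing, so batch
runs can skip empty lines gracefully.

`detect_peaks()` finds local maxima above a prominence threshold
(default 0.1 in normalized units) with a minimum mutual separation
(default 5 nm; the higher peak wins). Two numerical choices matter:

* **Plateau centring.** Noiseless slab profiles have exactly flat tops.
  A naive "first sample of the plateau" convention biases every peak
  position by half the plateau width (several nm for an 8 nm sheet), so
  runs of equal samples are collapsed to a single peak at the run
  centre; the lower-index rule is retained only for choosing the run's
  representative sample.
* **Sub-sample refinement.** Isolated (non-plateau) maxima are refined
  by a 3-point parabolic fit, bounded to ±half a step.

`peak_to_peak()` is the spacing metric; `profile_fwhm()` measures widths
at half *prominence* height with linearly interpolated crossings and
rejects truncated peaks. FWHM is a convention here: the original width
estimator was never operationally defined, so FWHM is adopted and used
consistently for sheets, belt slabs and fibrils.

## Morphometry and classification

`measure_ribbon()` and `measure_belt()` turn profiles into named
quantities using positional labelling: measurement lines run cytoplasm →
exterior, ribbon lines start between the membranes (first peak = OM,
later peaks = sheets), belt lines end between the membranes (last peak
= IM, earlier peaks = belt layers). The sheet/layer count is the modal
peak count across lines, and spacings are averaged over the lines with
that count. `classify_configuration()` applies the strict 40 nm
boundary: an OM-to-closest-sheet distance > 40 nm is `loose`, anything
else (including exactly 40) `tight`.

Width and fibril lines are placed transversely. Two placement choices
are deliberate:

* width lines run along the tilt axis, so missing-wedge elongation
  (which acts along the beam) cannot inflate width recovery — the same
  reasoning the artifact claims above impose on real measurements, where
  widths *are* contaminated and must be read as overestimates;
* the fibril line uses a small averaging depth (3 nm instead of the
  10 nm default). Averaging deeply across a cylinder mixes chords of
  the circular cross-section and biases the FWHM low by ~1.5 nm; a
  shallow window keeps the profile close to a transect through the
  fibril centre.

One caution on FWHM under blur: for slab-like (top-hat) profiles, blur
can only widen the FWHM — that is the defocus-overestimation property,
and it is tested over sigma ∈ {0, 1, 2, 4} nm. For a *disc* cross-section
the rounded profile loses its shoulders under blur, and the numerical
continuous-limit oracle shows the FWHM of an 11 nm cylinder under a
2 nm blur is ≈ 10.3 nm, slightly *below* the true diameter. Fibril
estimates under blur should therefore be read as "within the blur
uncertainty", not as strict upper bounds; the tests assert exactly
that.

## Lamella census geometry

For biofilms milled into thin lamellae, `cell_depth()` converts the
in-plane distance `d` from a cell centroid to the leading edge
(perpendicular point-to-line distance, `leading_edge_distance()`) into
true depth below the original sample surface, `depth = tan(a) · d`,
with `a` the milling angle. `census()` summarises annotated cells:
density (cells/μm²), occupancy (summed annotated cell area over lamella
area — an area fraction, which is what one section supports, so it is
called occupancy rather than a volume), and both `live_fraction` =
live/(live+dead) and `live_dead_ratio` = live/dead. Both are emitted
because published "live-to-dead ratio" figures are ambiguous between
the two whenever dead cells are present; neither is privileged.

## The statistical protocol

`compare_groups()` implements the gated dispatcher used for tomogram
measurement groups: Shapiro–Wilk normality per group at α = 0.05 (the
gate level itself is a convention; n < 3 forces the nonparametric
path), an SD-ratio > 2 homoscedasticity gate (again a convention — the
source protocol names the gates but not their thresholds), then
Student/Welch t or exact Mann–Whitney for two groups, ANOVA + Tukey or
Kruskal–Wallis + Dunn (Bonferroni-adjusted) for more.

`exact_mann_whitney()` enumerates the null permutation distribution of
the rank-sum statistic (mid-ranks for ties) whenever the smaller group
has ≤ 10 observations, and reports the probability of a deviation from
the null mean at least as large as observed — for the symmetric
rank-sum null this equals doubling the smaller tail. The analytically
forced case is two samples of 3 and 23 in complete separation:
2/C(26,3) = 2/2600 ≈ 0.00077, which prints as 0.0008. An exact
one-sample Wilcoxon signed-rank test (`one_sample_wilcoxon()`,
generating-function enumeration over all 2^n sign patterns, zero
differences dropped) covers the sheet-count comparison design, where
n = 21 values all above the reference give p = 2/2²¹ < 0.0001. Larger
designs fall back to tie-corrected normal approximations and are
flagged as such.

## Recovery experiments and their scale

`run_recovery()` drives the validation loop: per variant and replicate
(seed = `base_seed` + replicate index), render → image → annotate with
the canonical lines → measure → compare with ground truth;
`recovery_table()` condenses the result into one row per quantity with
a pass flag at the package's recovery tolerances (2 nm for tight
spacings, 5 nm for the loose offset, 3 nm for widths, 2 nm for the
fibril diameter). The shipped experiments use 20 replicate seeds for
the stochastic recoveries at canonical imaging and a single noiseless
identity replicate for the deterministic width/fibril recoveries —
sizes chosen so a full validation cycle, including the test suite,
completes in minutes on a laptop core while the replicate SD of every
recovered spacing stays well below the tolerance it is judged against.

```{r recovery-example, eval = FALSE}
rec <- run_recovery(c("tight", "loose"), n_replicates = 20, base_seed = 1)
recovery_table(rec)
autoplot(rec)
```

## What passing recovery does and does not show

The phantoms reproduce the *geometry* of the measured system and the
three dominant imaging artifacts, under which the pipeline recovers
every canonical spacing to well under a nanometre. Real tomograms add
everything the generator deliberately leaves out: membrane curvature,
ribbon flexibility and partial sheet occupancy, crowded periplasmic
densities adjacent to the peaks of interest, CTF oscillations rather
than a monotone blur, non-white noise, and operator variability in line
placement. Recovery success therefore validates the measurement
operators and their conventions — not the claim that any particular
real-data number is exact. The same caveats the artifact model encodes
apply to interpretation: widths measured off-axis are inflated by the
wedge, and all thickness-like quantities under defocus are
approximate upper bounds.
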