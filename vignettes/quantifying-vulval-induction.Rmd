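---
title: "Quantifying anchor-cell polarity, alignment and vulval induction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying anchor-cell polarity, alignment and vulval induction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acquant)
```

## The measurement problem

In *C. elegans* vulval induction, the anchor cell (AC) secretes the EGF
ligand LIN-3 toward the vulval precursor cells (VPCs) P3.p–P8.p lying on
the ventral midline. Four quantities characterise the system per animal:
the dorso-ventral and VPC-directed polarity of a fluorescent reporter in
the AC (`I_DV`, `I_AP`), the relative AC-to-P6.p alignment (`R`), the
per-VPC MPK-1 activity read out by an ERK kinase-translocation reporter
(KTR), and the vulval induction count. This vignette explains how
`acquant` computes each, which parameters matter, what the synthetic
generators emulate, and which design decisions were genuinely open.

Conventions used throughout: voxel arrays are ordered `(z, y, x)`;
ventral is increasing `y` and anterior is decreasing `x`; public
coordinates are 0-based and ranges half-open, matching the image formats
the package reads and writes rather than R's 1-based indexing (the
conversion happens internally, once).

## Polarity indices

The per-animal chain is projection → segmentation → background
subtraction → index:

* **Projection.** `sum_projection()` sums the slab spanning the AC.
  Sums (not means or maxima) keep the projection linear in the stack, so
  intensity ratios downstream are ratios of photon totals.
* **Segmentation.** `segment_ac()` computes an Otsu threshold inside a
  window around the nucleus seed (default half-width 24 px; windowing
  keeps other fluorescent cells in the frame out of the histogram), keeps
  the 8-connected supra-threshold component containing the seed, and
  fills holes. Failure modes (no supra-threshold pixel, seed below
  threshold) are distinct error classes carrying the threshold used.
* **Background.** `subtract_background()` removes the median intensity
  outside the mask. The median is used because the background estimate
  must be robust to the bright in-cell tail; the subtraction is clamped
  at 0 and is idempotent on its own output. Background removal must
  precede the index: any constant offset inside the mask pulls a ratio
  of means toward 1 (this is a regression test).
* **Index.** `polarity_index()` splits the mask pixels by the line
  through the AC nucleus centroid perpendicular to the chosen axis and
  returns the ratio of half mean intensities. Pixels exactly on the
  split line are excluded from both halves — the only unbiased
  tie-break. A line through the nucleus centre need not bisect the mask
  area, so both half areas are reported and an imbalance above 25% is
  flagged for review rather than silently accepted. For `I_AP`,
  "proximal" is the half toward the nearest VPC as determined by the
  geometry module; the caller names the side, because the AC may sit
  anterior or posterior of its target.

Classification thresholds default to 1.1 (ligand reporter) and 1.2
(PIP2 membrane marker), the values used for cohort "percent polarized"
summaries; both are strict (`>`), so an index exactly at threshold is
not polarized.

## Alignment and staging

`alignment_index()` implements `R = d(AC, target) / d(target, ref)` with
the reference VPC chosen by side: P5.p when the AC is anterior of the
target, P7.p when posterior, an exact tie going (with a log message) to
the anterior side. Distances are centroid-to-centroid Euclidean
distances in the projection plane in micrometres — the annotation format
does not record cell outlines, and the VPC row is nearly collinear with
the AP axis, so planar centroid distances match the measurement scheme.
R is a ratio of distances, hence invariant under rigid motion and
uniform scaling, which the tests assert at 1e-9.

`classify_alignment()` is a step function with the two breakpoints kept
strict exactly as printed: aligned when `R ≤ 0.09`, misaligned when
`R > 0.4`. `stage_from_gonad_length()` bins gonad length with half-open,
lower-inclusive bins (30–70, 70–110, 110–150 µm); the printed ranges
touch at 70 and 110 µm without resolving the boundary, so
lower-inclusive was fixed once and documented. Out-of-range lengths get
an explicit label rather than an error, because staging is annotation,
not validation.

## Biosensor ratios

`measure_nuclear_ratio()` segments each VPC nucleus on the red (H2B)
channel only — the green channel's nuclear level varies with the very
activity being measured, so segmenting on it would bias the mask — and
applies the identical mask to summed projections of the five central
slices around the nuclear focus. Activity is the nuclear mean red/green
ratio; simultaneous rescaling of both channels cancels, so only the
red:green contrast matters. `normalize_profile()` divides each ratio by
the P4.p–P8.p mean of the same animal (no single VPC can be assumed
unaffected, so none serves as the reference), giving profiles with mean
exactly 1; P3.p is excluded structurally because it adopts a VPC fate in
only about half of all animals. `call_highest_p6p()` requires a strict
maximum; exact ties count as "not highest", the conservative direction
for cohort fractions.

## Induction statistics

`vulval_index()` is total induced cells over animals scored; per-animal
counts support steps of 0.5, the traditional scoring granularity for
half-induced VPCs. Per-animal phenotype classification is strict against
3. `bootstrap_mean()` implements the resampling scheme used for cohort
summaries: resamples of size n with replacement (default 10,000), s.e.m.
as the SD of resample means, and a percentile 95% CI. The percentile
flavour is the default because it respects the bounded, discrete support
of induction counts; a normal-interval variant (mean ± 1.96 s.e.m.) is
available and the choice is recorded in the result.

Of the test battery, Welch/Student t, the variance F and Spearman
correlation delegate to R's stats machinery. Fisher's exact test and
Mann–Whitney are implemented in the package: the Fisher p sums
hypergeometric probabilities not exceeding the observed table's, and
Mann–Whitney switches at a combined n of 12 between full enumeration of
group assignments over pooled mid-ranks (a permutation test, so ties are
exact) and a tie- and continuity-corrected normal approximation, with
the method recorded per result. All tests are two-sided, and no
multiple-testing correction is applied — results are reported
per-comparison, and that is stated rather than hidden. The test suite
cross-checks both exact tests against independent enumeration oracles
and against `stats::fisher.test()` / `stats::wilcox.test()`.

## What the generators emulate

`generate_ac_stack()` builds a rasterized ellipsoidal AC (default
semi-axes 8 × 11 × 11 voxels at 0.13 × 0.1 × 0.1 µm in a 21 × 64 × 64
crop) over a flat background. Three choices deserve explanation:

* **Polarization is a two-compartment step**, not a gradient: the
  measured indices are two-compartment mean ratios, so a step in
  expected intensity makes the generator's `rho_dv`, `rho_ap` the exact
  noiseless ground truth for them. Ground truth reports the
  background-free compartment means over the rasterized voxel halves
  (background is subtracted downstream, so these are the recoverable
  quantities); voxels exactly on a split plane are excluded from both
  halves, mirroring the index computation.
* **The radial profile is cortical.** The reporter being emulated sits
  on the basal cortex and in intracellular punctae, so the default
  profile is a 3-voxel (~0.3 µm) cortical shell at `base_intensity`
  (200 photons/voxel) with a diffuse interior at 20% of that
  (`interior_fraction = 0.2`; setting it to 1 gives a uniform solid).
  Because the profile is radially symmetric it cancels exactly from the
  compartment mean ratios. This matters for the measurement chain: a
  uniform solid ellipsoid projects with a 1–16 voxel thickness ramp, and
  a single Otsu threshold then cuts inside the cell asymmetrically
  between the bright and dim halves, which no thresholding segmenter
  survives unbiased. The cortical profile projects much flatter, and the
  pipeline recovers `rho_dv` ∈ {1, 1.2, 1.5, 2} with a median error
  within 5% at the default noise level (asserted in the tests over 100
  seeds per level).
* **Punctae do not bias the truth.** Punctae are Gaussian blobs
  (σ = 1.2 voxels) confined to the mask, placed uniformly inside the
  ellipsoid, with amplitudes scaled by the local compartment factor.
  Uniform placement with *constant* amplitude would add an unpolarized
  intensity floor and drag every expected ratio toward 1; scaling the
  amplitudes keeps the expected image proportional to the step profile.

Noise is Poisson on (signal + background, default 20 photons) followed
by Gaussian read noise (SD 3), the standard camera model at moderate
photon counts. Every generator is a pure function of (params, seed);
per-channel and per-animal streams are split deterministically from one
seed, and bit-identical reproduction is tested.

`generate_biosensor_image()` writes five spherical nuclei in two
channels with nuclear green set to `red / activity`, so the injected
activity vector *is* the noiseless nuclear red/green ratio vector,
recovered by the measurement chain to 1e-6 without noise and called
correctly (highest-in-P6.p) in ≥ 95% of noisy replicates at the default
noise level. `generate_induction_cohort()` draws per-animal fate
patterns (wild-type, hyperinduced, hypo-induced, shifted primary fate)
and induced counts from per-pattern distributions; the default
distributions put most mass on mild deviations (3.5–4 induced cells for
hyperinduced, 2–2.5 for hypo-induced), the way partially penetrant
vulval phenotypes are typically scored. With all probability on
wild-type, every animal has count 3 and VI is exactly 3 — the
definitional anchor of the induction index.

What the generators deliberately do **not** emulate: optics (no PSF,
no diffraction, no depth-dependent attenuation), deconvolution
artefacts, autofluorescence structure, nucleus shape irregularity, VPC
row curvature, or correlated animal-to-animal variability. Passing
tests therefore demonstrate that the measurement chain is correct and
well-calibrated on images matching its geometric assumptions — not that
segmentation will succeed on arbitrary real micrographs, where focus,
debris and neighbouring cells dominate failure rates.

## Problem sizes and numerical choices

The test suite runs 100 simulated animals per polarization level for
parameter recovery, 200 noisy replicates for biosensor call recovery,
2,000 null replicates for the type-I error of the two-sample tests, and
10,000-animal cohorts for generator frequency checks — sizes at which
the binomial/bootstrap tolerances asserted are meaningful while the
whole suite stays around a minute. Numerical edge cases are resolved
explicitly rather than left to chance: empty half-compartments and
zero-denominator means raise distinct error classes; the central-slice
window for even k puts the extra slice below the focus; boundary
truncation of that window warns instead of erroring; 16-bit integer
TIFFs round-trip bit-identically while float stacks round-trip at
float32 precision with the scale factor recorded in the sidecar.

## Known limitations

* The AC split line comes from the nucleus centroid, which need not
  bisect the mask; the area-imbalance flag marks affected animals but no
  correction is attempted.
* Otsu-based segmentation still erodes a thin dim rim of the object;
  the residual median bias on `I_DV` at strong polarization
  (`rho_dv = 2`) is about −4% under default conditions.
* Mann–Whitney p-values for large samples with heavy ties rely on the
  tie-corrected normal approximation; the exact path is limited to
  combined n ≤ 12 by enumeration cost.
* The pipeline quantifies single time points; translocation kinetics,
  cell tracking and 3-D (unprojected) polarity metrics are out of scope.
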