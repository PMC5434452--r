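---
title: "Projection-based quantification of flow-chamber adhesion assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projection-based quantification of flow-chamber adhesion assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chamberflow)
```

## The measurement problem

In a parallel-plate flow chamber, leukocytes (here: monocytes) are perfused
over a protein-coated substrate at a controlled wall shear stress and imaged
by phase-contrast time-lapse microscopy. Cells interacting with the substrate
appear as bright circles on a dark background; cells carried in the free
stream are above the focal plane and effectively invisible. Two behaviours
must be separated and quantified per field of view:

* **firm adhesion** — a cell that remains stationary on the substrate for at
  least the whole acquisition window (operationally: 4 s);
* **rolling** — slow, receptor-mediated translation along the flow axis, much
  slower than the free stream.

`chamberflow` implements the classical projection-based workflow for this
separation. Given a stack of $N$ frames $I_1,\dots,I_N$ acquired over
duration $T$:

* the **snapshot** is a single frame (frame 0 by default); every in-focus
  cell, adherent or rolling, appears in it. Its count is the total $n_\text{tot}$.
* the **minimization image** is the per-pixel temporal minimum
  $M^-(p)=\min_k I_k(p)$. A bright cell survives only at pixels its footprint
  covers in *every* frame, so exactly the cells stationary for the whole
  window remain; its count is $n_\text{adh}$.
* rolling cells are obtained by subtraction,
  $n_\text{roll} = n_\text{tot} - n_\text{adh}$ (clamped at 0 and flagged if
  the detector ever returns a negative difference).
* the **maximization image** $M^+(p)=\max_k I_k(p)$ turns each rolling cell
  into an elongated blur covering every position it visited. The blur length
  divided by $T$ is that cell's average rolling velocity; only blurs with
  visible start *and* end points (not touching the image border) are
  measured, which geometrically caps measurable velocity at
  (field extent along flow)/$T$ — about 112 µm/s for the default
  446 µm / 4 s geometry.

Counts are normalized to densities per mm² of substrate (default field:
0.594 × 0.446 mm = 0.264924 mm²; six fields per chamber, aggregated as the
mean of per-field densities).

## Acquisition model and defaults

`acquisition_config()` captures the acquisition: 30 frames/s for 4 s
(120 frames), a 594 × 446 µm field, 0.6 dyn/cm² (= 0.06 Pa) wall shear
stress. Two conventions deserve explanation:

* **Flow axis.** The flow is taken along the 446 µm axis (image rows). This
  choice makes the geometric velocity cap 446/4 ≈ 111.5 µm/s, matching the
  ~112 µm/s cap the workflow is known for; the 594 µm axis would imply
  ~149 µm/s.
* **Pixel calibration.** The true camera calibration of any given microscope
  is instrument-specific, so it is a configuration field (default 1 µm/px,
  giving 594 × 446 px rasters), never a hard-coded constant. The same holds
  for bit depth (`max_gray`, default 255).

## The synthetic scene generator

Because donor-derived image data cannot be regenerated, validation rests on
a synthetic generator with complete ground truth. `generate_field_stack()`
renders a scene of cells into a stack:

* **In-focus cells** are discs of radius 5 µm (a ~10 µm monocyte) with peak
  intensity 120 above a uniform background of 30 (8-bit scale) and a soft
  sigmoidal edge of width 0.5 µm, so footprints have sub-pixel structure
  rather than aliased hard edges.
* **Rolling cells** translate along the flow axis at a constant, imposed
  velocity. Frame sample times span the window inclusively
  ($t_k = kT/(N-1)$), so the centroid displacement over the stack equals
  $vT$ exactly and a roller's blur extent equals path length + cell
  diameter. With times $t_k = k/f$ the last frame would fall $1/f$ short of
  $T$ and every recovered velocity would be biased low by $v/N$ — an error
  of up to ~0.9 µm/s at the cap, larger than the velocimetry tolerance we
  want to guarantee.
* **Free-stream cells** are rendered with a Gaussian defocus of σ = 8 µm and
  peak 15: strongly blurred, low contrast, below the detector's contrast
  gates — emulating cells transported above the focal plane.
* **Noise** is additive i.i.d. Gaussian per pixel and frame (default σ = 4
  gray levels in pipeline runs, i.e. a ~30:1 peak SNR typical of
  phase-contrast at these magnifications), followed by clipping to
  [0, `max_gray`] and integer quantization (camera digitization).
* **Adherent jitter.** "Stationary" means velocity exactly 0; an optional
  sub-pixel thermal jitter (< 0.5 px) can be added, small enough that
  adherent cells still survive the minimization projection.
* **Determinism.** A stack is bit-identical for identical
  (scene, config, noise, seed). Field-level seeds are derived from the donor
  seed by a fixed affine rule modulo 2³¹−1 (`field_seed()`), so any single
  field can be regenerated independently.

Ground truth follows the snapshot convention: cells are counted if their
centre is inside the field at frame 0; cells entering later are rendered but
not counted.

### Cohort presets

`cohort_preset()` draws whole donor groups. Group means for the
control and LPS-pre-stimulated young/old cohorts use the published summary
statistics of the assay being emulated (adherent densities 15, 19, 19, 26
per mm²; rolling densities 15, 16, 15, 14 per mm²; velocities 28.7, 27,
30.3, 27 µm/s). Donor-to-donor spread is reconstructed from the reported
SEMs: donor SD = SEM·√n with n = 16 (young) or 14 (old), the cohort sizes
the SEMs summarize; per-field counts are then Poisson around the donor
expectation × field area, and per-cell velocities are normal around the
group mean (cell SD 8 µm/s, which across the ~150–200 cells measured per
condition reproduces a velocity SEM of ~0.5–0.6 µm/s), truncated to
(0, cap). The uncoated, antiCD11c and Mg²⁺ presets have no printed means;
they encode the qualitative pattern those conditions show (adhesion at
background level without collagen or with the integrin blocked; adhesion
equalized across age at ~21/mm² after outside-in Mg²⁺ activation) and are
documented as representative values, not reproductions.

Gender labels mirror the emulated cohorts (10F/6M young, 6F/8M old); they
are metadata only — no gender-stratified inference is performed.

## Detection choices

The source workflow was manual counting in an image viewer; any automated
detector must therefore make choices the original method never specified.
All of them are exposed in `detector_config()`:

* **Threshold.** Otsu's method on the image histogram — parameter-free and
  well suited to bimodal phase-bright images — with a floor at
  background + 3·noise, both estimated robustly (median and MAD of the
  image). The floor prevents Otsu from splitting the noise distribution on
  images that contain no bright object.
* **Shape gates.** Area 25–400 µm² (discs of ~6–22 µm diameter) and
  circularity $4\pi A/P^2 \ge 0.6$ (clamped at 1; rasterized perimeters make
  the raw ratio exceed 1 for small discs). Streak candidates in the
  maximization image instead require elongation (major/minor extent) ≥ 2.
* **Contrast gate.** A detection's mean intensity must exceed the background
  estimate by 30 gray levels; this is what makes defocused free-stream cells
  (peak contrast ~15) invisible to the detector, as they are to the eye.
* **Clump splitting.** A component larger than twice the nominal cell
  footprint $\pi(d/2)^2$ (d = 10 µm default) can only be fused cells and is
  split by one round of watershed on the distance transform. The trigger is
  deliberately relative to the *nominal* footprint, not the maximum area
  gate: a two-cell dumbbell (~190 µm²) must split, while watershed leaves a
  clean single disc untouched (one catchment basin). Counts, not shapes, are
  the output of interest.
* **Counting convention.** A detection counts if its centroid is inside the
  field; border-touching discs count (unlike streaks, whose completeness
  filter is a correctness requirement, not an edge-effect choice).

## Velocimetry choices

Streak extents are Feret-style: the major length is the longest chord
(computed on the convex hull of the component's pixel centres, + 1 px for
pixel extent), the minor width the maximal perpendicular extent. Because a
disc of diameter $d$ translating a distance $L$ paints a blur of extent
$L + d$, three conversion modes are provided:

* `"corrected"` (default): $v = (\text{major} - \text{minor})/T$. Using the
  streak's *own* width as the diameter estimate self-calibrates against the
  threshold: however wide the thresholded footprint came out, the same bias
  enters major and minor extents and cancels, and a stationary disc's
  implied velocity is exactly 0.
* `"diameter"`: subtract the configured mean cell diameter (10 µm).
* `"raw"`: $v = \text{major}/T$, the strict historical convention (blur
  length over time), retained for faithful reproduction; it overestimates
  by $d/T$ (2.5 µm/s at defaults).

Measurements above the geometric cap are flagged `over_cap` and excluded
from summaries as segmentation artefacts. Merged blurs from overlapping
lanes are detected by a width profile along the major axis: a component with
an interior run of bins wider than 1.5× its median width is flagged
`ambiguous` and excluded — the automated analogue of discarding ambiguous
blurs by eye. Two cells sharing an identical lane are fundamentally
indistinguishable in a projection; that is a limitation of the method
itself, not of this implementation. Orientation is not gated by default
(flow alignment is assumed); an optional |orientation| ≤ 15° gate exists.

## Statistics

Donor-level inference mirrors the assay's reporting conventions:

* **Normality gate.** Shapiro–Wilk at α = 0.05 per group ("column
  statistics"); degenerate samples (n < 3 or zero variance) fail the gate.
  If both groups pass, an unpaired two-sided Student's t test (equal
  variances; Welch available) is used; otherwise the Mann–Whitney U test,
  exact for small untied samples (both n ≤ 8), else the tie-corrected
  normal approximation with continuity correction. If every observation in
  both groups is identical the comparison short-circuits to p = 1.
* **Two-way ANOVA** with interaction on age × LPS uses Type II sums of
  squares, appropriate for the unbalanced 16/14 design when main effects
  are the question; Type III is available. An all-constant response returns
  F = 0, p = 1 rather than 0/0.
* **Significance symbols** follow the star convention: ns for p > 0.05 and
  `*`, `**`, `***`, `****` at p ≤ 0.05, 0.01, 0.001, 0.0001.
* **LPS response** is the per-donor ratio of stimulated to control adherent
  density; its per-group variance quantifies the homogeneity of the
  response. Expression fold changes use the standard $2^{-\Delta\Delta C_t}$
  arithmetic with B2M as the reference gene; since the age-group comparison
  names no calibrator, the mean ΔCt of the young group is the natural
  calibrator choice.

## What the tests do and do not show

The validation suite runs entirely on synthetic data at these problem
sizes: 100 random small stacks for the projection oracle (bit-exact match
against a per-pixel loop); 50 random noiseless full-size scenes for exact
count recovery; 100 rendered rollers at 10–100 µm/s for velocity recovery
within 2 px/T (0.5 µm/s); 2000 null replicates per test route for type-I
error; 1000 null replicates for ANOVA p-value uniformity; 200 donors per
group for preset self-consistency (means within 2× the nominal SEMs).

Passing these shows the *pipeline* is correct and unbiased under its own
image model: uniform background, ideal discs, linear additive Gaussian
noise, imposed constant velocities. Real phase-contrast stacks additionally
contain illumination gradients, halo artefacts, focus drift, cells that
pause or detach mid-window, and platelet/debris objects — none of which the
generator emulates (background subtraction and flat-field correction are
deliberately out of scope). Results on real data therefore depend on gate
tuning in `detector_config()`, and the velocity caps/flags should be
monitored rather than assumed clean. Velocities are imposed, not emergent:
no shear-dependent bond kinetics, cell deformation or hydrodynamics is
simulated, so the generator validates measurement, not biology.
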