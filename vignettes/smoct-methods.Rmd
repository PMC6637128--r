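---
title: "Speckle-modulating OCT in silico: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speckle-modulating OCT in silico: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(smoct)
```

## The problem

Spectral-domain optical coherence tomography (SD-OCT) resolves tissue
reflectivity in depth by Fourier-transforming a spectral interferogram. The
coherent summation of many sub-resolution scatterers inside each resolution
cell produces speckle: a multiplicative, granular noise whose intensity is
exponentially distributed and whose contrast (standard deviation over mean)
is 1 in a homogeneous region. Speckle hides exactly the structures
neuroimaging cares about — myelinated fascicles of 40-80 um, cortical-layer
banding, and the intensity step at a brain-tumor margin.

Speckle-modulating OCT (SM-OCT) inserts a rotating ground-glass diffuser at
a conjugate image plane. Each acquired frame then carries an independent
realization of the local illumination phases, so successive frames have
uncorrelated speckle patterns; averaging M of them in linear intensity
reduces speckle contrast by 1/sqrt(M) without sacrificing resolution, depth
of field, or field of view. Because tumor tissue is myelin-poor and weakly
scattering, the de-speckled image separates dark tumor from bright brain by
intensity alone, and the margin can be delineated at roughly the lateral
sampling scale (~10 um).

This package implements the whole chain as testable software: synthetic
neural-tissue phantoms with known ground truth, a physics-based forward
model of the spectrometer and diffuser, conventional reconstruction with
sharpness-optimized dispersion compensation, linear-scale compounding with
speckle statistics, the post-processing chain (vessel-shadow gain, 3-D
anisotropic diffusion, histogram equalization, isotropic resampling, surface
flattening), and tumor-margin/layer metrics scored against the phantom's
ground truth.

## The forward model

For the A-scan at lateral position $x_j$, frame $m$ and spectral sample
$k_i$ (wavenumber, rad/um), the detected intensity is

$$I_m(k_i) = E(k_i)\,\Bigl|1 + \sum_s a_s T_s w_s\,
e^{i[2 k_i n z_s + \phi_s + \phi_{s,m} + a_2(k_i-k_0)^2 + a_3(k_i-k_0)^3]}
\Bigr|^2 + \varepsilon$$

* $E(k)$ — Gaussian source envelope, 1300 nm center, 170 nm FWHM, sampled
  uniformly in wavelength (1024 samples by default, spectrometer
  convention); the wavenumber grid is therefore non-uniform and
  reconstruction must k-linearize.
* $a_s$ — scatterer amplitude; $\phi_s$ — fixed uniform random phase;
  $w_s$ — Gaussian lateral beam weight with 9 um intensity FWHM.
* $T_s$ — cumulative amplitude transmission through vessel cylinders above
  the scatterer (vessels backscatter nothing; they only attenuate, which
  produces the depth shadows the enhancement stage removes).
* $\phi_{s,m}$ — the diffuser perturbation of frame $m$.
* $a_2, a_3$ — polynomial spectral dispersion phase (rad um^2, rad um^3).
* $\varepsilon$ — additive zero-mean Gaussian noise on the spectral
  intensity, clamped at zero.

The reference-arm amplitude is fixed at 1 and scatterer amplitudes are kept
well below 1, so the autocorrelation (scatterer-scatterer) terms are
simulated but negligible. Depths are optical path lengths; the medium group
index defaults to 1 so tests read depths directly in microns.

**Diffuser model.** The physical diffuser is a pupil-plane phase screen; the
pipeline only depends on one property of it — the controllable frame-to-frame
speckle correlation — so the model perturbs each scatterer's phase directly.
Frame 1 draws i.i.d. uniform(-pi, pi) phases; each subsequent frame keeps
each phase with probability rho and redraws it otherwise. The complex-phasor
correlation between consecutive frames is then exactly rho in expectation:
rho = 1 is conventional OCT (diffuser removed, frames identical), rho = 0 is
ideal SM-OCT. The grit-to-correlation mapping of a real diffuser is not
derivable from first principles here and is deliberately exposed as the
single parameter rho.

## Phantoms: a stated world

A phantom is an ordered list of region descriptors in a block of tissue
(units microns; z is depth): cortical layers (slabs with per-layer density
and reflectivity), fascicles (bright cylinders, 40-80 um diameters),
tumors (dark ellipsoids with optional finger-like projections along +x,
emulating margin interdigitation along axonal tracts), and vessels (pure
attenuators). Scatterer counts are Poisson(density x region volume),
positions uniform, amplitudes Rayleigh with the region's mean reflectivity
as mean — with uniform phases this yields a circular Gaussian field and
hence fully developed speckle by construction.

Two semantics deserve a note:

* **Overlap means replacement.** A later-listed region replaces earlier
  tissue at overlapping points: a scatterer survives only if the region that
  generated it is the one that labels its position. Without this, a
  myelin-poor tumor placed inside a bright cortical layer could never be
  darker than its surroundings — regions would only ever add backscatter.
  For non-overlapping regions the total count remains exactly the sum of the
  per-region Poisson draws.
* **Density sets two different regimes.** About 20 scatterers per 9x9x4 um
  resolution cell (~0.06 per um^3) is enough for fully developed
  single-frame speckle, and is the default for margin and layer phantoms.
  It is *not* enough for deep compounding studies: the compound converges to
  the tissue's expected backscatter map, whose Poisson granularity at 20 per
  cell has ~24% contrast and floors the sqrt(M) law near M = 16. Real tissue
  has 10^3-10^4 sub-resolution scatterers per cell. Contrast-law phantoms
  therefore use 2.5 per um^3 (~10^3 per cell, static texture ~4%), with
  amplitudes ~5e-4 so scattering stays weak and autocorrelation terms remain
  negligible.

Ground-truth label volumes assign each voxel center the label of the last
region containing it. Regions that protrude beyond the extent (e.g. a huge
ellipsoid emulating a half-space tumor for planar-margin studies) get their
in-extent volume estimated by Monte Carlo and are sampled by rejection.

## Reconstruction

Per A-scan: subtract the frame-set mean spectrum (background and DC
removal), interpolate onto a uniform k grid spanning the same range (natural
cubic spline — a linear operator, built once per grid and applied to all
A-scans), apodize (Hann by default; the PSF oracles use the same window),
apply the compensation phase, inverse Fourier transform, keep the
positive-depth half, and store magnitude squared as linear intensity. The
axial pixel pitch follows from the uniform grid, pi/(K dk) — about 1.16 um
for the 1300/170 source regardless of K; K sets the depth range.

Numerical choices worth knowing:

* **Axial resolution convention.** `axial_psf_fwhm()` measures the FWHM of
  the *magnitude* A-scan. This is the convention under which a Gaussian
  source obeys the textbook closed form (2 ln2/pi) lambda0^2 / d_lambda
  (~4.4 um in air at 1300/170); the intensity-squared peak is narrower by
  sqrt(2). Measured in-air width (no window): 4.34 um, 1.2% from the closed
  form.
* **Analytic-signal step.** The complex-conjugate half of the spectrum is
  suppressed before the compensation phase is applied. With zero
  compensation this is exactly equivalent to keeping the positive-depth half
  afterwards (bit-identical output); with strong compensation it prevents
  the doubly-dispersed mirror term from smearing across the image.
* **Interpolation roll-off.** Spline k-linearization attenuates fringes near
  Nyquist: single-reflector peak intensity is flat to ~45% of the depth
  range and drops to ~0.75 at 80%. Quantitative ROIs in the tests are kept
  in the shallow half; strongly chirped spectra (dispersion studies) use a
  larger K so the chirp stays below half Nyquist.
* **Dispersion estimation.** Coarse-to-fine grid search (21-point grids, 3
  levels, each level re-gridding over two coarse steps around the incumbent)
  minimizing the Shannon entropy of the normalized intensity image; ties
  break toward smaller |a2| + |a3|. On noiseless point targets it recovers
  an injected a2 = 500 rad um^2 to well under 1%. The original study's
  compensation algorithm is unspecified; entropy minimization is a standard
  stand-in.

## Compounding and speckle statistics

Compounding is the voxelwise arithmetic mean of per-frame volumes in linear
intensity — the sigma/mu = 1 and 1/sqrt(M) laws do not hold on log-scaled
data, so log compression is display-only and flagged. `speckle_contrast()`
reports mean, sd, contrast and effective looks 1/C^2; `contrast_vs_frames()`
fits the slope of log C against log M, which is -1/2 for uncorrelated
frames. With the diffuser off (rho = 1) averaging identical speckle changes
nothing — the OCT control branch.

## Enhancement chain

Fixed order (each stage independently callable): vessel-shadow gain, then
3-D anisotropic diffusion, then histogram equalization. Quantitative metrics
are always computed before equalization.

* **Shadow gain.** Per lateral position, gain = clamp(T/m, clip) with m the
  column's depth-mean and T the field-of-view mean of m; where unclipped the
  post-gain depth-means are equal to machine precision. The source study is
  ambiguous about per-position vs per-plane gain; per lateral position is
  the literal reading of "uniform along the field of view". Clip default
  10x, protecting empty columns; clipped columns are counted and reported.
* **Anisotropic diffusion.** Explicit 6-neighbour Perona-Malik with
  exponential conductance exp(-(g/kappa)^2), zero-flux boundaries,
  dt = 1/7 (stability bound 1/6), 10 iterations; kappa auto-set to the 90th
  percentile of neighbour differences. Antisymmetric fluxes conserve the
  global mean to round-off and enforce an extremum principle. The study
  names only "anisotropic diffusion"; iteration count, kappa and dt are
  package defaults, not reported facts.
* **Histogram equalization.** Global, on dB-scaled data (-80 dB floor), with
  a piecewise-linear cumulative-histogram mapping onto [0, 1]: monotone
  non-decreasing and nearly exactly uniformizing. Bin count (256) and the
  global-vs-adaptive choice are package defaults.
* **Isotropic resampling.** Separable trilinear interpolation to cube voxels
  (default 4 um), with extents preserved within one voxel.
* **Flattening.** Per column, the surface is the first depth at which the
  axially smoothed intensity exceeds half of the column's maximum; the
  surface map is median-filtered (5 px) and columns are shifted by integer
  voxels to a constant plane, zero-padded. The study's flattening algorithm
  is not described; this is the package's own operationalization.

## Margin and layer metrics

En-face slabs average a stated depth window below the flattened surface
(default 50-150 um, configurable; desk-scale tests use shallower windows to
match their reduced depth range). `segment_tumor()` applies an Otsu
threshold — tumor is the below-threshold class — removes small components,
fills holes, and refuses slabs whose "dark" class is not convincingly darker
(mean ratio above 0.5), returning an empty mask with a warning.
`extract_margin_curve()` traces the largest component's boundary with a
marching contour at level 0.5 after a 3x3 box smoothing; the smoothing makes
the contour track the edge with sub-pixel accuracy and removes the
staircase bias on curved margins (a binary circle's traced perimeter is
within ~2% of 2 pi r) while leaving straight edges in place by symmetry.
`margin_error()` pools point-to-polyline distances in both directions
(penalizing over- and under-segmentation equally) and reports the mean and
95th percentile in microns. The ~10 um delineation claim has no operational
definition in the source study; this symmetric distance is the package's
own, and the acceptance property asks for <= 2 lateral pixels (12 um at 6 um
pitch) on a seeded planar-margin phantom, plus a strict improvement over the
single-frame branch.

`layer_profile()` summarizes a flattened volume by the lateral mean at each
depth, per-band mean/sd between supplied (or auto-detected) band edges, and
the adjacent-band CNR $|\mu_1-\mu_2| / \sqrt{(\sigma_1^2+\sigma_2^2)/2}$.
One subtlety: the phantom module defines region reflectivity as the mean
scatterer *amplitude*, and mean image intensity scales with density times
the mean-square amplitude. A "2:1 reflectivity" layer pair in the
backscattered-power sense is therefore built with amplitude means in ratio
sqrt(2):1, and the band-mean intensity ratio then reconstructs 2:1 (measured
2.03 on the acceptance phantom).

## Protocols and the synthetic world's scale

`protocol_spec()` bundles a phantom with an acquisition configuration; the
two named presets mirror the source study's settings — volumes at 6 um
lateral spacing with 18-40 averages, dense B-scans at 4 um with 100
averages. `run_protocol()` executes phantom, frames, reconstruction,
compounding, enhancement and metrics deterministically under one seed and
optionally persists volumes (float TIFF), the frame set, the contrast table
(CSV) and a JSON metrics report; the `smoct` CLI script wraps the same
functions. Tests run desk-scale versions (reduced sample counts, fields of
view and frame counts, stated in each test) — full-scale volumes are
configuration-reachable but not exercised by the suite.

What a green suite does and does not establish: the phantoms emulate
layered, fascicle-bearing, tumor-bearing neural tissue as piecewise-
homogeneous Poisson scatterer fields with controllable speckle
decorrelation. They do not emulate multiple scattering, depth-dependent
attenuation in tissue, focus/confocal gating, polarization, motion, or
calibrated tissue scattering coefficients (the study gives none), so green
tests validate the method's statistical and geometric behavior — not
biological realism of absolute intensities.

## Known limitations

* The spectral-domain sensitivity roll-off of the spline k-linearization is
  stronger than a real spectrometer's pixel-integration roll-off; deep-ROI
  quantitative work should increase K or restrict depth.
* Vessel axes are treated as infinite lines for the attenuation chord; make
  vessels span the volume.
* The diffuser's rho is phenomenological — there is no mapping from physical
  grit size or tangential speed.
* Frame sets persist via R serialization (no HDF5 bindings in the target
  environment); volumes use a minimal self-contained float TIFF
  reader/writer.
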