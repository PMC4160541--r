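---
title: "Through-time spiral GRAPPA for single-breathhold 3D cine: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Through-time spiral GRAPPA: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the acquisition and
reconstruction model it implements, the parameters that matter, what the
synthetic data generator does and does not emulate, and the design choices
made where the method leaves latitude.

## Acquisition model

The dynamic scan is an ECG-gated 3D stack-of-spirals bSSFP cine: a
variable-density spiral readout in-plane, Fourier (partition) encoding along
the slab, one partition encode per heartbeat, so the whole ventricle is
covered in a single breathhold of one RR interval per encoded partition.
In-plane, only every sixth interleaf is acquired per partition and
timeframe (8 of 48 at full scale), giving a temporal footprint of
`arms_acquired * TR` per cardiac phase (35 ms at TR 4.4 ms). A separate
ungated, free-breathing scan acquires all interleaves in every partition,
repeated (10 times, 34 s) as calibration data.

The spiral arm is designed analytically in k-space: an Archimedean-type
spiral whose radial pitch follows an effective-arm-count profile
`n_eff(|k|)` rising smoothly (smoothstep over one centre-radius) from
`center_arms` (4) inside the centre region (the central 8 × 8 of the
matrix) to `arms_total` (48) at the designed edge
`k_max = matrix / (2 FOV)`, with samples placed at constant arc-length
increments. Both the radial line spacing and the along-readout spacing are
held at `margin / FOV` with `margin = 0.88`, chosen so that even the
worst-case *sample-to-sample* distance between adjacent arms (line spacing
plus half an arc step in quadrature) stays inside one Nyquist interval.
Gradient and slew waveforms are not modelled: the reconstruction consumes
sample coordinates only, and the rewinder played after the useful readout
is represented by the short post-edge tail that truncation discards. With
the full-scale parameters the designed readout reaches the k-space edge in
about 1.9 ms at a 5 µs dwell (the dwell default comes from
1 / (1563 Hz/px × 128 px)). k-space is carried in physical cycles/mm
throughout (the image grid is in mm, so phases are dimensionless);
normalized cycles/FOV are a documented conversion, not the internal unit.

Density compensation is geometric: for a constant-arc-length spiral the
Voronoi-like cell of a sample is, to first order, its local arc spacing
times the distance to the azimuthally adjacent *acquired* arm, which the
package computes exactly as a point-to-polyline distance and clips at the
designed k-space edge. The weights therefore sum to the sampled disc area
`pi k_max^2` (the tests check 5%) and equal the analytic area element
`(margin/FOV)^2` in the uniform outer region. Note that for this sampling
law the outer-region weights are approximately *constant*, not proportional
to `|k|` — the radial-ramp intuition applies to constant-angular-rate
spirals, which this is not. Coincident samples (all arms start at k = 0)
share their cell instead of failing.

## Reconstruction

**Calibration.** Each missing sample is synthesized from its two flanking
acquired arms at three readout offsets (−1, 0, +1) across all channels:
`2 × 3 × n_channels` unknowns per target channel. Kernel geometry is
presumed constant over 1 arm-gap × 8 readout-point segments, so one weight
block is calibrated per (acquired-arm gap, missing-arm offset, readout
segment) — kernels are *not* shared between rotated gaps, because
non-Cartesian GRAPPA kernels are not rotation invariant. The least-squares
system stacks one equation per (repetition × partition × segment point):
1280 equations at full scale. Calibration acts on the raw kz-partition
samples *before* any transform — partitions are valid independent
calibration instances only pre-FFT. The solver is complex QR; a
rank-deficient or underdetermined block falls back to the minimum-norm
pseudo-inverse solution with a warning, and an optional Tikhonov ridge
(default 0, i.e. plain least squares) is available for very noisy desk
experiments. Source readout offsets are *clamped* at the ends of the
readout (the first/last valid neighbour is reused); wrapping the readout
would splice unrelated k-space locations.

**Application.** Acquired samples are never altered (the tests check
bitwise identity); each weight block is reused at exactly the same spiral
sampling location in every partition encode and every timeframe. The whole
fill is linear in the dynamic data.

**Gridding.** The non-uniform Fourier transform is evaluated exactly as a
dense matrix (an NUDFT): at this package's target sizes (up to 128²
in-plane) one BLAS multiply per (partition × channel) batch is fast, the
operator is built once per trajectory and cached, and forward/adjoint are
exact adjoints by construction — which the density-compensation scaling and
the adjoint tests rely on. Adjoint gridding is scaled by the voxel area so
a uniform object keeps its intensity. The partition direction uses a
centred orthonormal DFT (DC at `floor(n/2)+1`); slab oversampling is
discarded symmetrically, an odd surplus dropping the extra slice on the
high-z side.

**Coil combination.** Walsh-style adaptive combination: channel covariance
per 8 × 8 in-plane block with 50% overlap, principal eigenvector as matched
filter, Hann-window blending; with covariance `R = X^H X` the eigenvector
estimates `conj(s)/||s||`, so the combined signal is `X v`. Intensity
normalization is available but **off by default**: lacking a body-coil
reference, the shading estimate must come from the data itself. The
implementation models the log of the block-eigenvalue map by a quadratic
polynomial in all three coordinates (exact for Gaussian-lobe coil profiles)
fitted robustly (IRLS, bisquare) over the support of the combined image, so
localized anatomy is treated as outliers and only the global shading trend
is divided out. On a uniform object with pronounced lobes this demonstrably
flattens shading better than root-sum-of-squares; on anatomy with mild
shading no reference-free normalization is reliable, brightening edges
instead (the known chest-wall artifact of normalized non-Cartesian
reconstructions), which is why the quantitative pipeline defaults to the
plain matched filter.

## The phantom and what passing tests mean

The generator emulates: a beating LV (half-ellipsoidal cavity below a fixed
base plane, isotropically scaled so the cavity volume follows
`V(t) = V_ED (1 − 0.63 sin²(πt))` — ED at phase 0, ES at mid-cycle, EF
exactly 63%, matching the healthy-volunteer mean), an incompressible
myocardial shell of constant volume (120 mL, EDM 126 g at the conventional
1.05 g/mL), a torso of background tissue, smooth complex Gaussian-lobe coil
maps on a ring (deterministic geometry), slab-direction partition encoding
with 25% oversampling at desk scale, rigid respiratory translation
(10 mm peak, predominantly head–foot) with a random cardiac phase per
calibration repetition, and complex Gaussian sample noise. Desk-scale
defaults — FOV 280 mm at 64², 24 arms (4 acquired at R = 6), 8 channels,
8 + 2 partitions of 8 mm, 10 cardiac phases, EDV 150 mL — keep a full
simulate–calibrate–reconstruct–analyze cycle to a few minutes on one CPU
while preserving the method's structure; the full-scale protocol is reached
by overriding configuration keys. The "noisy" condition sets the k-space
noise so a single-coil image has blood SNR 15, propagated analytically
through the density-compensated adjoint.

Simplifications to keep in mind: calibration cardiac phases are drawn from
the phantom's discrete phase grid rather than a continuum; respiration is a
rigid translation (no deformation, no through-plane anatomy change); there
is no bSSFP signal-equation or off-resonance banding simulation (banding is
summarized by the 1/TR interval arithmetic only), no flow or in-flow
enhancement, no arrhythmia, and the anatomy is geometric. Passing tests
therefore demonstrate the correctness and conditioning of the
reconstruction chain and the analysis arithmetic — not clinical image
quality on real anatomy.

The base plane of the LV sits on a partition boundary so Simpson voxel
counting is unbiased by a half-filled basal slice; with that choice the
rasterized masks agree with the closed-form volumes to better than 2% at
128² and the reconstruction recovers EF within fractions of a percentage
point noiselessly.

## Analysis stage

Blood-pool segmentation thresholds at the blood–myocardium midpoint: the
blood plateau is the median of voxels above 60% of the 99.9th percentile
(robust to Gibbs overshoot), and the threshold is `0.65 ×` plateau — for
tissue plateaus `b` and `m`, a band-limited edge crosses `(b + m)/2` at the
true boundary, and the phantom's myocardium sits at 0.3 b. ED/ES are the
volume argmax/argmin with earliest-phase tie-breaking. Masks are voxel
containers in mL (`voxel volume × count`, summed over contiguous slices);
epicardial masks, when present, must contain the endocardial ones.

Agreement statistics follow the conventions used for method comparisons:
Bland–Altman limits use the fixed 1.96 multiplier (not a t quantile) with a
two-sided one-sample t-test on the bias; Welch's t-test delegates to
`stats::t.test` (the closed form is an independent oracle in the tests);
the Wilcoxon signed-rank test is implemented in-package because exact
mid-rank tie handling below n = 26 is required — zero differences are
*discarded* (the classical treatment; the alternative that retains them is
not implemented), tied absolute differences receive mid-ranks, the exact
two-sided p comes from the generating-function convolution over doubled
ranks, and beyond n = 25 a normal approximation with tie-corrected variance
and continuity correction takes over.

## Numerical and interface choices

Protocol arithmetic rounds half away from zero to the printed precision
(35.2 → 35 ms, 33.79 → 34 s, 227.27 → 227 Hz), since that is how protocol
sheets report values. The encoded partition count applies the oversampling
fraction, rounds up, then rounds up to the next even integer — that keeps
the partition DFT symmetric and reproduces 16 encoded partitions from
12 + 33%; whether scanners use exactly this rule is unknowable from the
printed numbers, so it is a documented convention. Raw multi-channel
samples travel in a serialized container with fixed dataset names,
dimension order `(readout, arm, channel, partition, frame)` and declared
permutations that the reader undoes; images are written as 4D NIfTI with
voxel sizes in the header; reports are JSON; every pipeline run re-writes
its resolved configuration next to its outputs and all randomness flows
from the single seed.

## Limitations

Desk-scale EF recovery uses a global threshold on a phantom with known
tissue plateaus; real data needs contours (the analysis stage consumes
masks precisely so that manual or external segmentations can be plugged
in). The exact-NUDFT gridding trades memory (a dense complex matrix) for
kernel-error-free transforms and would need a kernel-based NUFFT well
beyond 256² matrices. Off-resonance deblurring, view sharing, iterative
reconstruction and partition-direction acceleration are deliberately out of
scope.
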