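---
title: "Models and methods behind knobtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind knobtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knobtools)
```

This vignette is the package's own account of its science: the models
implemented, the tunable parameters and why their defaults are what they
are, the numerical decisions, and the limits of what the synthetic-data
tests establish.

## Coordinate and intensity conventions

All stacks are 3D arrays ordered `(z, y, x)` with a physical voxel size
`(dz, dy, dx)` in nanometres; the center of 0-based voxel `(z, y, x)` sits
at `((z + 0.5) dz, (y + 0.5) dy, (x + 0.5) dx)`. Every distance rule in
the package (the 0.2 µm grouping rule, knob volumes, proximity cutoffs)
is evaluated in physical units through the voxel size, never as voxel
counts, so anisotropic sampling is handled uniformly. The default voxel
size is `(125, 40, 40)` nm — typical for reconstructed 3DSIM stacks of
this instrument class, and chosen so the 0.2 µm rule spans five lateral
voxels; reconstructed voxel sizes vary between set-ups, so every entry
point accepts the true size. "Above threshold" means strictly greater
throughout.

Stacks are written one channel per file as multipage TIFFs. The installed
TIFF codec stores 32-bit samples in `[0, 1]`, so intensities are divided
by a scale factor recorded in a JSON sidecar: integer-valued stacks use
the full 32-bit code range and round-trip exactly; other stacks use a
power-of-two scale and return with relative error below 1e-9. A scene
(channels acquired together) is a directory with a `manifest.json` tying
the channel files and ground truth together — a deliberate alternative to
multichannel TIFF, whose dialects are ambiguous across software.

## Flexible iterative thresholding

The automatic threshold is the isodata fixed point: starting from the
global mean, `t` is replaced by the midpoint of the means of the two
classes it induces until the update falls below 1e-6 of the dynamic
range (at most 500 rounds; convergence is monotone in practice because
the intermeans map is contractive on unimodal-pair histograms). The
iteration runs on raw intensity values rather than a binned histogram —
the images are small, and exactness on two-level images makes the
behaviour easy to reason about; the test suite uses an independent
1,000-bin histogram implementation as the oracle.

The flexible threshold `T = t + d (m1 − t)` moves `t` toward the mean
`m1` of the above-threshold class under a single unitless parameter
`d ∈ [0, 1]`. It is the identity at `d = 0`, reaches `m1` at `d = 1`, and
is non-decreasing in `d` because `m1 ≥ t` always. The package default is
`d = 0.5`, the midpoint of the family; the right value is
image-character-dependent and the parameter is exposed everywhere,
including a free `--threshold-override` in the CLI for a fully manual
choice.

## Channel registration

The transform family has seven parameters: translations in nm, one
rotation about the optical (z) axis, and three magnifications. Per-axis
lateral magnifications are needed because each channel passes through its
own focusing optics, whose astigmatism scales the two lateral axes
differently. The composition order is fixed and serialized with the
parameters: scale about the stack center, rotate about z through the
center, then translate. `apply_transform()` is a pull-back — the output
voxel at physical position `q` takes the input intensity at `T(q)`,
interpolated trilinearly — so the estimated transform maps the
mis-registered observation onto the reference. The exact inverse of a
transform with unequal lateral magnifications contains a shear and leaves
the 7-parameter family; `invert_transform()` therefore returns a general
affine map rather than re-approximating.

`estimate_transform()` maximizes Pearson correlation between the
reference and the resampled moving stack. Three numerical decisions
matter, all visible in the code and validated in the tests:

1. **Pre-filtering.** Both stacks are smoothed with a one-voxel Gaussian
   before the search. Trilinear resampling smooths the moving image's
   noise by an amount that depends on the fractional voxel offsets, which
   biases raw-image correlation toward transforms that maximize that
   smoothing; a common pre-filter makes the differential effect
   negligible.
2. **A fixed correlation support.** The correlation runs over a fixed
   voxel set chosen once per fit: voxels that stay in-frame under *every*
   transform within the search bounds, restricted to the top 15% of
   smoothed reference intensity. A support that changed with the
   parameters would let the optimizer profit from shrinking it; the
   intensity restriction discards background voxels that carry almost no
   registration information but dominate the cost.
3. **Two-stage bounded refinement with a cubic polish.** Translations are
   seeded at the integer-voxel FFT cross-correlation peak; all free
   parameters are then refined by bounded quasi-Newton (L-BFGS-B) in a
   normalized space (voxels, 0.1°, 1e-3 magnification units), first with
   the trilinear sampler, then with a tricubic Catmull–Rom sampler. The
   cubic stage exists because trilinear interpolation error at marginal
   axial sampling (σ_z ≈ dz) biases the axial magnification estimate by
   a few parts in 10⁴ — visible as an off-truth peak in the noise-free
   correlation profile — and the cubic kernel reduces that error by an
   order of magnitude.

Default search bounds are ±500 nm translation, ±1° rotation, ±0.005
magnification; the estimate is rejected if it leaves them, and the
returned correlation is never below that of the initial guess.
`refine_translation()` re-optimizes only the translations from a bead
calibration, because specimen-dependent chromatic aberration (coverslip
thickness, depth) moves mostly the translations, particularly along z;
rotation and magnifications pass through bit-exactly.

On synthetic bead fields (150–300 beads, 32×96×96 to 32×128×128 voxels),
parameter recovery is well within a quarter voxel per translation axis,
0.1° in rotation, and 1e-3 per magnification, noise-free and at
signal-to-noise 20. Axial magnification is the least identifiable
parameter: its information content scales with the axial field extent, so
thin stacks (under ~25 z planes) should not be trusted to calibrate `m_z`
at the 1e-3 level.

## Segmentation and grouping

Nuclei are 26-connected components (the paper-family convention for 3D
blob objects; 6-connectivity splits diagonal bridges created by
anisotropic voxels) of the DAPI channel binarized at the flexible
threshold. Components smaller than a 400 nm-radius sphere are treated as
speckles and dropped — an explicit package decision, configurable, since
noise speckle handling is otherwise unspecified. An all-zero stack
segments to an empty list rather than an error.

Cross-channel grouping uses the 0.2 µm rule with *edge-to-edge* distance:
the distance transform of the nucleus mask (exact Euclidean, anisotropic
spacing) is evaluated at the voxels of each candidate object and the
minimum taken. Centroid distance would mis-group large nuclei. An object
within range of two nuclei is assigned to both and flagged ambiguous
rather than arbitrated; objects grouping to no nucleus are reported
separately.

## The overlap statistic

Per nucleus, each channel crop is normalized as
`max(x − t, 0) / (max3 − t)`, with `max3` the mean of the three brightest
voxels *of the nucleus object* (not the whole crop — the crop can contain
a neighbouring object's tail). Averaging three voxels buffers residual
noise; reconstruction has already removed salt-and-pepper noise, so three
suffice. A consequence kept deliberately: the single brightest voxel can
normalize slightly above 1. The statistic below is scale-free, so this
has no effect, and clipping would discard information.

Both normalized images are zero-padded to 250× their voxel count and the
overlap is `n = Cov(G′, B′) / sqrt(V(G′) V(B′))` with population moments
over the padded arrays. Padding pushes the means toward zero, so `n`
approaches the Manders-form ratio `ΣGB / sqrt(ΣG² ΣB²)` while remaining
exactly 1.0 for identical images at any finite padding. The padding is
evaluated in closed form — zeros change no sums, so the padded moments
are functions of the unpadded sums and the padded length — and the tests
verify agreement with materialized padded arrays to 1e-12. Negative
values of `n` (possible only as roundoff around disjoint supports) are
clamped to 0. The form is symmetric in G and B; the asymmetric Manders
coefficients `k1` and `k2` are reported alongside so either reading of
"overlap of G with B" is recoverable.

In thresholded mode the two channels get independent flexible thresholds
computed within the crop with the same `d`; in unthresholded mode
`t = 0`. Thresholded mode isolates the labelled object but inherits the
interpretive choice of `d`; unthresholded mode is assumption-free but
compresses differences because the weak background enters both channels.
The synthetic tests show exactly this compression (marker weights 0.9 vs
0.3 separate by ~0.09 thresholded, ~0.01 unthresholded).

## Knob calling, frequency and proximity

Published knob counts were obtained visually. The automated caller here
is therefore a surrogate whose every criterion is a package decision,
validated against synthetic ground truth only and never claimed to
reproduce published mutant tables: smooth the DAPI crop with an
anisotropic Gaussian (60 nm lateral / 150 nm axial sigma — half the PSF,
suppressing voxel noise without erasing a 300 nm body), take voxels at
least 2 within-nucleus standard deviations above the within-nucleus mean,
form 26-connected components, and keep those between a 150 nm-radius
sphere and 5% of the nucleus volume with mean raw intensity at least
1.5× the within-nucleus median. On default synthetic scenes the caller
finds the single planted knob in ≥95% of 50 seeds with centroids within
150 nm of truth, and calls anything in ≤5% of knob-free scenes. Below
the default z-score cutoff the candidate region can exceed the volume
ceiling and suppress calls, so the call count is guaranteed monotone in
the cutoff only from the default upward.

`knob_frequency()` reports class counts (0, 1, 2, ≥3 knobs) and
percentages to one decimal, always computed from the raw counts.
`locus_knob_proximity()` restricts to knob-containing nuclei and scores a
nucleus proximal when the minimum edge-to-edge distance between any locus
object and any knob component is strictly below 0.2 µm.

## The expression chain

The chain follows the one-colour array design: median of spots per probe;
detection when the mean `gIsWellAboveBG` exceeds 0.55; a single scalar
normalization pinning the 75th percentile at 2,500 (percentile by linear
interpolation between order statistics — the anchor holds under any
percentile definition because one scalar factor is applied); division by
gene copy number (integer copy numbers enforced); paralog correction;
geometric-mean combination of biological replicates; ratio to the control
strain with log2 ratios; strict two-fold gene sets; χ² goodness-of-fit of
category compositions against the all-probe expectation (delegated to
`chisq.test` with explicit expected proportions).

Paralog correction assumes every mismatch attenuates hybridization by the
same factor α, the minimal model consistent with equal-effect mismatches.
A perfect-match probe for gene A of a pair with `m` mismatches between
the paralogous sequences measures `s_A + α^m s_B`; a correction probe
carries one extra mismatch and measures `α (s_A + α^m s_B)` — exactly α
times its perfect-match probe — so α is estimated as the mean
correction/perfect-match ratio (or supplied globally), and the 2×2 linear
system solves for the cross-hybridization-free signals. `m = 0` makes the
system singular and is rejected; negative solutions are floored at zero
and flagged. The correction is linear, so it commutes with the scalar
normalization, and the noise-free chain recovers planted fold changes to
relative error below 1e-6. Surrogate overrides for genes whose residual
signal is known to be pure cross-hybridization (e.g. deleted histone
genes) are supplied by the user as a named vector, not hard-coded.

## The synthetic-data generators

`generate_nucleus_scene()` emulates what the analysis consumes —
*reconstructed* images — not the optics: channels are blurred with an
anisotropic Gaussian PSF (FWHM 120 nm lateral, 300 nm axial, the stated
resolution of the modality), then mis-registered (resampled under the
inverse of the channel's true transform, so registering with the true
parameters restores alignment), then given Poisson noise (gain 0.1
photons per intensity unit, i.e. SNR ≈ 10 at the default intensity of
1,000) plus Gaussian read noise. Nuclei are 2 µm spheres; chromatin
texture is a smoothed lognormal field (correlation length 100 nm,
log-s.d. 0.15 — chosen once so that 3σ texture excursions stay near
1.6× the median, keeping a planted 2.5×-median knob "conspicuous", which
is the defining property of the real structure; a rougher texture would
contradict the premise that knobs stand out). Knobs are 300 nm-radius
spheres at 2.5× median density; silent foci are 150 nm-radius peripheral
regions at 0.6× median; a locus channel plants one compact focus per
nucleus, adjacent to the knob with a configurable probability. Marker
channels mix the chromatin template with an independent lognormal field
according to a colocalization weight `w`, making the expected overlap
monotone in `w` — verified over `w ∈ {0, 0.25, 0.5, 0.75, 1}`.

Neither knob density nor knob volume is a published number; they are free
parameters of the generator, and results on synthetic scenes validate the
*machinery* (segmentation recall, caller sensitivity/specificity,
monotonicity, parameter recovery), not any biological claim. Real 3DSIM
data differ in ways the generator does not model: reconstruction
artifacts (negative ringing, honeycomb patterns), spectral bleed-through,
depth-dependent aberration, nuclear shape irregularity, and visual-count
subjectivity. Passing tests therefore establish correctness of the
computations, not equivalence to the published measurements, which derive
from real microscopy.

`generate_bead_field()` renders PSF-sized Gaussian beads at uniform
positions and the same beads at their transformed positions (widths
scaled by the magnifications) as the moving stack, plus optional noise —
the analytic construction avoids passing the ground truth through the
very resampling code under test. `generate_probe_table()` draws lognormal
transcript abundances, plants up-regulated genes above the 85th abundance
percentile and down-regulated genes below the median (so planted changes
cannot move the order statistics the 75-percentile anchor interpolates
between, keeping noise-free fold recovery exact), applies the paralog
forward model, a per-replicate array scale factor, and lognormal spot
noise. All three generators are pure functions of `(params, seed)` and
restore the caller's random stream.

## Problem sizes in the routine test suite

The suite runs single-CPU in a few minutes: bead fields of 32×96×96
voxels with 150 beads for the 20-draw registration recovery (and one
32×128×128, 300-bead field at SNR 20), 50 + 50 default scenes for knob
caller sensitivity and specificity, 20 five-nucleus scenes for
segmentation recall/precision, 60 single-nucleus scenes for the planted
proximity fraction, and 600-gene arrays for the expression chain. These
sizes are the package's choices for routine validation; all generators
scale to larger studies through their parameter objects.

## Known limitations

- The registration model has one rotation axis and global magnifications;
  field-dependent distortion is out of scope.
- Axial magnification calibration needs an adequate axial extent (see
  above).
- The knob caller's thresholds are tuned to the synthetic texture model;
  applying it to real images should start from a re-examination of the
  z-score and volume windows against a visual count on a pilot set.
- Touching nuclei are not split (no watershed); the segmenter assumes
  interphase cells at plating densities where nuclei are disjoint.
- The attenuation model α^mismatches treats all mismatches equally;
  position- or base-dependent effects are absorbed into the fitted α of
  each pair.
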