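---
title: "Continuous-rotation electron diffraction with credkit: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous-rotation electron diffraction with credkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

credkit implements the offline computational core of a semi-automated
continuous-rotation electron diffraction (cRED, also marketed as MicroED)
acquisition system together with a SerialED crystal-screening front end:
detector geometry correction, beam-centre estimation, lens-distortion
correction, the defocus-tracking acquisition schedule and every
integration-geometry number derived from it, a CNN pattern classifier
with isolated-crystal selection, writers for SMV/TIFF/MRC and for
XDS/DIALS/REDp instruction files, per-frame intensity-scale quality
control, and a rotating-crystal simulator that supplies ground truth for
all of it. Live microscope and camera control, the GUI, and running the
integration programs themselves are out of scope.

# Detector geometry

The Timepix detector is a 2x2 tiling of 256x256 modules whose
module-boundary pixels are physically three times wider (165 um vs
55 um). `expand_timepix()` maps a raw 512x512 readout onto a 516x516
grid of uniform logical pixels: each wide pixel becomes three logical
pixels, splitting its counts equally (1/3 each; 1/9 over a 3x3 block at
the central corner). Equal splitting conserves integrated intensity
exactly, which keeps quality-control sums meaningful; the strips are
masked for integration anyway. The alternative — copying the counts to
all three logical pixels — would triple the apparent intensity of the
strips and was rejected.

The expanded strips cover 0-based logical indices 255..260 in each
dimension. `cross_untrusted_rectangles()` emits them in the XDS
open-interval convention (`x1 < x < x2`, 1-based), i.e.
`255 262 0 517`; a golden-file test pins the emitted numbers.

Flatfield correction divides by a mean-normalized response map; pixels
with non-positive response are dead and forced to zero. Whether the
acquisition software applied an extra gain term for the wide pixels
beyond the geometric split is not documented anywhere we could verify,
so none is applied here.

# Beam centre

Two estimators serve different stages:

* `center_gaussian_max()` (processing): arg-max of the Gaussian-smoothed
  frame. The usual smoothing sigma is 10-30 px; the default is 10 px,
  the sharp end, which localizes best on clean synthetic data. Borders
  use reflect padding; ties break to the lowest row, then column.
* `center_top_percentile()` (screening): centroid of the top 5%
  brightest pixels. Every pixel tied at the threshold intensity is
  included, so a constant frame yields the geometric centre.

Integration software expects a stationary beam, so per-frame estimates
are reduced by `median_center()` — a component-wise median, robust to
fewer than half the frames being outliers. The median is taken on
corrected (516x516) frames; taking it before or after distortion
correction is not distinguishable from the published description, and
the correction is sub-pixel at the centre.

# Elliptical distortion

Post-specimen lenses map a true circle of scattering angles into an
ellipse; an eccentricity of 0.22 (axis ratio 0.9755) is typical of the
instrument this workflow was built on. `fit_elliptical_distortion()` is
the numerically stable Halir--Flusser formulation of the direct
least-squares ellipse fit, with input centring/scaling for conditioning;
noiseless recovery is better than 1e-3 in eccentricity and 0.2 px
Gaussian jitter on the points still recovers 0.22 within 0.01. Only the
eccentricity is published for the reference instrument; the azimuth of
the major axis is a free parameter (default 0 deg, configurable).

The correction is the affine stretch of the minor-axis component by
`a/b`; `geo_corr_tables()` encodes the per-pixel displacement in integer
hundredths of a pixel, the convention the XDS `X-GEO_CORR`/`Y-GEO_CORR`
instructions expect. The tables are written as SMV images with
`TYPE=signed_short` (our own reader round-trips them bit-exactly; XDS
itself stores such tables as unsigned shorts, so regenerate through XDS
tooling if byte-level compatibility with a particular XDS build
matters).

# Acquisition schedule and exclusion bookkeeping

During acquisition the goniometer rotates continuously; every
`n_interval`-th diffraction pattern is replaced by a defocused snapshot
of the crystal used for re-centring (defocus tracking). `build_schedule()`
lays out cycles of `n_interval` data slots followed by one
defocus-tracking slot; a trailing partial cycle has no tracking slot.
The published frame counts (554 data/55 tracking, 430/43) force this
10:1 reading of "every nth pattern", and we follow it. Every slot —
including tracking slots, whose exposure is only ~0.01 s — occupies a
full `frame_time` (default 0.512 s: 0.5 s exposure plus readout and
overhead), because the gap must sweep exactly one frame's oscillation
for the integration software's oscillation angle to stay consistent; the
remaining slot time models refocus settling. A 0.2 s start delay avoids
goniometer acceleration and backlash and shifts the time origin only.

The oscillation angle for integration is the rotation range divided by
the data-collection time, times the slot duration. On the published
(rounded) inputs of the reference data sets this formula reproduces the
logged values to one unit in the fourth decimal; the formula is
implemented as stated rather than the printed roundings.

`excluded_ranges()` enumerates maximal runs of tracking slots (1-based,
inclusive) for `EXCLUDE_DATA_RANGE`; `dials_exclusions()` provides the
same information as the `scan_range`/`exclude_images` parameters. The
two sets provably partition `[1, n_slots]` (tested by enumeration over
all schedules with up to 200 data frames and intervals up to 12).
Tracking slots keep placeholder frame numbers in `DATA_RANGE`, so the
exclusion indices align with slot indices; the snapshots themselves are
written to a sibling directory.

# Screening

`preprocess_pattern()` is the fixed pipeline the classifier sees: locate
the beam (top-5% centroid), crop 400x400 px around it (zero-padding
outside the frame, so the beam stays centred near borders), cap
intensities at mu + 4 sigma with the moments computed on the crop, scale
to [0, 1] (all zeros if the image has no contrast), and shrink to
150x150 by area averaging (preserves the integrated-intensity character
of spots better than point sampling). The full pipeline is not
idempotent — re-cropping a 150x150 output into a 400x400 zero-padded
window and re-capping necessarily changes values — but the
normalization and resize stages are, and the tests check exactly that.

`cred_cnn()` trains the good/bad classifier with the screening protocol:
batches of 75 images, 20 epochs, dropout rate 0.15, binary cross-entropy
and RMSprop; rectifier activations everywhere except the logistic
output. A score strictly greater than 0.5 means "good" (a tie at
exactly 0.5 classifies bad). The nominal architecture is four 3x3
convolution blocks of 32/64/128/128 filters, each followed by 2x2
max-pooling, then a 128-unit dense layer — and it is configurable,
because no reference description of the layer table is available and
because CPU budgets matter: the acceptance-scale test trains the same
four-block shape at 1/16 width (2/4/8/8 filters, dense 8), which on one
CPU core completes the full 20-epoch protocol on a 4000-image corpus in
roughly ten minutes. No deep-learning framework exists in the target
environment, so the network is implemented directly: fused nine-tap
convolution kernels in C++ (im2col+GEMM is slower here — the GEMM
shapes are too skinny for BLAS to be efficient), with all randomness
(initialization, shuffling, dropout) drawn from the R RNG so a seed
makes training bit-reproducible.

`isolation_filter()` applies the selection rules: a crystal is kept only
if its nearest neighbour is at least 1.5 um away (both members of a
closer pair are discarded) and it is at least 0.5 um from every frame
edge. `write_candidates()` emits the screening CSV with the canonical
column order (image path, image and crystal sequence numbers, prediction
score with four decimals, object size, stage x/y); units of object size
and stage coordinates are micrometres.

# Quality control

Integration programs report a per-frame scale factor that weakens when
the crystal drifts (partially) out of the selected-area aperture.
`scale_series()` emulates that behaviour with a specifiable statistic
rather than replicating any program's internal estimator: summed counts
outside a central-beam exclusion disc (default radius 30 px) and outside
the masked cross, normalized to a series median of one. The statistic is
invariant under global intensity rescaling and permutes with the frames.
`tracking_flags()` flags frames below a dip threshold (default 0.5) and
declares a series "poorly tracked" if at least `run_length` (default 5)
consecutive frames are flagged or the coefficient of variation exceeds
0.3; a single-frame spike (e.g. a grid bar shadowing the pattern at high
tilt) is flagged but does not fail the series.

# Simulator: what it emulates, what it does not

`simulate_rotation_series()` renders kinematic diffraction: reciprocal
lattice points within an excitation tolerance (default 0.002 1/A) of the
Ewald sphere at each slot's angular midpoint, projected with the
small-angle relation r = L*lambda/d (exact to well under a percent at
electron wavelengths), drawn as Gaussian spots with a triangular
partiality profile in excitation error, an overall-displacement damping
`exp(-b_iso |s|^2)`, Poisson counting noise, a central beam blob, a flat
instrument background and a diffuse crystal-scatter level (default
2 counts/px) that scales with the illuminated crystal volume — the
inelastic/amorphous halo real crystals produce, and the reason the
summed-counts quality-control statistic tracks crystal obscuration at
all (pure Bragg sums fluctuate with the partiality of the few strongest
spots). Crystal drift attenuates both the diffuse level and the
diffracted (not primary) intensity through the geometric overlap of the
crystal disc with the selected-area aperture (radii 0.75/0.35 um are the instrument's two
apertures); tracking slots render a defocused silhouette instead of a
pattern. Defaults describe a 10 A cubic cell at 200 kV, 250 mm camera
length, 55 um pixels.

It deliberately does not model dynamical scattering, inelastic
background, detector point-spread, beam damage or goniometer backlash.
A green recovery test therefore establishes that the estimators are
correct on clean kinematic data with Poisson noise — not that they are
robust to every pathology of real frames.

`simulate_pattern_classes()` produces class-separable screening stills
(sharp-spot patterns as the good class; powder rings, blanks and diffuse
scatter as bad classes — rings are treated as bad by default, which is a
configurable choice since reference labels for computer-generated rings
are not documented). Because the classes are separable by construction,
classifier accuracies on them are upper bounds: the published corpus
accuracies in the mid-90s came from 78 000 hand-labelled real patterns
with subjective labels and are not reproducible at a desk, which is why
the acceptance criterion here is a scaled-down proxy (accuracy > 0.90 on
synthetic classes), not a reproduction.

# Numerical and convention choices

* CODATA-2018 constants; voltages in kV, wavelengths in Angstrom.
* Wavelength printed with five decimals (0.02508 at 200 kV); angles with
  four decimals; frame numbering 1-based inclusive wherever XDS/DIALS
  conventions apply.
* SMV: ADSC-style keys, 512-byte header, little-endian unsigned shorts,
  counts clamped to [0, 65535]; MRC mode 2 (float32) so nothing clamps;
  TIFF baseline single-strip 16-bit with metadata as JSON in the
  ImageDescription tag.
* Output directories get an incrementing numeric suffix and are never
  reused.
* The maximum-resolution figure often quoted for a 250 mm camera length
  (~0.8 A) reflects an effective-magnification calibration that is not
  derivable from nominal geometry; camera length is treated as display
  metadata, and `resolution_at_radius()` uses the exact scattering-angle
  relation.

# Known limitations

The CNN is a faithful but minimal implementation — no data augmentation,
learning-rate schedules or checkpoint averaging. The distortion model is
a single affine (elliptical) term; higher-order fields are out of scope.
HDF5 export is not implemented. The QC statistic is an emulation with
the same sensitivity as the integration programs' scale factor, not a
reimplementation of their estimators.
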