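---
title: "Label-free colony sensing on quad microraft arrays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free colony sensing on quad microraft arrays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raftsense)
```

## The measurement problem

Adherent cell colonies — human induced pluripotent stem cells (hiPSCs) are
the motivating case — are nearly transparent in focused bright-field
microscopy, which makes label-free cytometry on structured culture
substrates hard: the substrate itself (here a quad microraft array, a grid
of releasable 200 × 200 μm polystyrene rafts seated in PDMS microwells)
contributes far more image contrast than the cells do. `raftsense`
implements a sensing stack that turns this around by exploiting one
physical asymmetry: **cell appearance changes with focus, the substrate's
appearance does not**. Bright-field z-stacks acquired at a few focal
offsets are reduced by a per-pixel standard deviation projection (SDP);
after subtracting a pre-seeding background scan of the same field, the
background-subtracted SDP (B-SDP) carries cell texture almost exclusively.

The package covers the full workflow around that idea:

1. **`synth`** — a scene generator that renders background/signal z-stacks
   of a quad array with exact, as-drawn ground truth;
2. **`preprocess`** — flat-field correction, intensity normalization, and
   subpixel rigid registration of the background scan onto the signal scan;
3. **`bsdp`** — the B-SDP enhancement and segmentation chain;
4. **`grid`** — microraft detection, row/column indexing, interpolation of
   missing sites, and tracking across timepoints;
5. **`cytometry`** — per-colony, per-raft coverage records, raft-count
   classification, segmentation metrics, biomarker area ratios, and
   doubling-time fits;
6. **`release`** — selection and nearest-neighbour routing of biopsy
   targets, and the closed-loop dislodgement controller run here against a
   simulated microneedle.

## The segmentation model

Let $I_k(x)$ be the corrected signal planes at focal offsets $z_k$ and
$B_k(x)$ the corrected background planes. After registering $B$ onto $I$
(rigid: subpixel translation plus a rotation searched over ±0.5°), the
B-SDP is

$$ S(x) = \mathrm{sd}_k\,\{ I_k(x) - B_k(T x)\}. $$

Cells appear in $S$ as punctate speckle with a bright perimeter halo; raft
rims and well edges survive only as long, straight residual lines. The
filter chain that turns $S$ into colony masks is, in order:

* **Oriented top-hats.** White top-hat with a 2 × 33 μm rectangle at 0° and
  at 90°, combined by pixelwise **minimum**. A straight edge survives the
  top-hat whose element lies parallel to it, so only the minimum of the two
  orientations suppresses edges in both directions while passing the
  isotropic cell speckle. (The combination rule is this package's choice;
  the oriented-rectangle sizes follow the published calibration of 1/6 of a
  raft side.)
* **Local entropy.** Shannon entropy of the quantized top-hat image over a
  14 μm-radius disk. Noise occupies a few gray levels, cell speckle many,
  so entropy converts scattered punctate signal into filled, nearly
  constant patches over cells. The image is min–max scaled before
  quantization, which makes the stage (and everything downstream) invariant
  to positive affine rescaling of the input stacks. The alphabet size is
  64 levels by default rather than a full 8-bit alphabet: the 14 μm disk
  holds only ~50 samples at the working pixel sizes, and an alphabet much
  larger than the sample count saturates the entropy estimator near
  $\log_2 n$ for noise and signal alike, collapsing the two modes. With 64
  levels the noise mode sits 2–3 bits below the cell mode across the 0.8–3.25
  μm/px range. (`entropy_levels` restores 256 if wanted.)
* **Opening by reconstruction** with a 40 μm disk: removes debris-scale
  entropy peaks while exactly preserving the shape of surviving colony
  plateaus.
* **Otsu threshold, hole filling, 8 μm contraction, majority filter,
  size exclusion.** All interior holes are filled by default (dense
  colonies have none that are real); the 8 μm inward contraction
  compensates the dilated appearance of cells in SDPs and is implemented
  as erosion with an 8 μm-radius disk — the stated intent is a uniform
  boundary correction, not topological thinning. The majority filter is a
  single 3 × 3 pass. Components smaller than a 25 μm-radius disk are
  removed as debris.

**Minimum-contrast guard.** Otsu always returns a threshold, even on a
cell-free field, where it would split noise fluctuations of the entropy
image into large percolating false components. `segment_colonies()`
therefore requires the between-class mean separation of the enhanced image
to exceed `min_contrast` (default 0.8 entropy bits) before any pixel is
declared foreground. The default sits between the separations observed on
noise-only fields (~0.2–0.4 bits) and on cell-bearing fields (~2 bits and
above), chosen from that noise analysis; blank scenes then segment to
exactly zero components, which the test suite asserts across seeds.

All structuring-element sizes are specified in micrometres and converted
to pixels at run time, so the chain is consistent across magnifications;
a dedicated test checks mask agreement (IoU ≥ 0.8) between renders of the
same scene at 1.625 and 3.25 μm/px.

## Grid indexing and tracking

Microrafts are segmented from corrected bright-field planes by Otsu
thresholding (rafts are brighter than PDMS), hole filling, border-object
removal, a debris pass that drops anything far below raft scale, closing
with a 20 μm disk — larger than half the 30 μm intra-quad gap, smaller
than half the 100 μm barrier, so the four subunits of a quad merge but
neighbouring quads never do — and size exclusion at 0.5–1.5× the nominal
quad area. The pre-closing debris pass matters: stray super-threshold
texture specks in the barrier can otherwise chain two quads together
through two closing hops.

Detected centroids closer than 430 μm (0.8 quad pitch) are consolidated by
single-linkage averaging. The lattice fit estimates orientation and pitch
robustly from nearest-neighbour displacement vectors (median of angles
folded mod 90°, median of lengths snapped to pitch multiples, one round of
3-MAD outlier rejection), de-rotates the centroids and refines the origin
from rounding residuals; each detection is then assigned the nearest
lattice index, with collisions resolved in favour of the nearest
detection. Missing sites are filled by piecewise-linear interpolation
along rows and columns in 8 mm (15-quad) segments — long enough to average
centroid jitter, short enough to follow smooth array distortion — and the
row and column estimates are averaged with equal weight. Timepoints are
tracked by registering each grid to the first with the median displacement
of mutually nearest detections and re-indexing on the reference lattice.

## The release controller

A quad is an eligible biopsy site when **more than one** of its rafts has
detected coverage **strictly above 50%**; among those rafts the one with
the least adjacent-PDMS outgrowth is targeted (such rafts detach most
cleanly, preserving the mother colony). Targets are ordered by a greedy
nearest-neighbour tour from the scan origin (ties broken lexicographically
— deterministic replays matter more here than tour optimality).

During release, the well is imaged before and after each microneedle
actuation. Pixels whose intensity changed materially between the frames —
|post − pre| above an Otsu threshold, floored at 15% of the pre-frame
dynamic range so pure noise never registers — are classified as change;
change inside the well footprint is cleared area, change outside is
material that left the well. The published description of this measurement
is ambiguous about polarity (the same super-threshold pixel class cannot
be both the dislodged area and the un-dislodged raft); this package
resolves it by taking the **remaining material** to be the unchanged,
light-blocking part of the footprint, the dislodgement extent to be
cleared area over well area, and the re-aim point to be the
intensity-weighted centroid of the remaining material, which makes the
80% success rule and centroid re-aiming mutually consistent. The loop
retries aiming at that centroid and halts on: extent > 0.8 (success),
residual-centroid displacement > 70 μm from its initial position
(cumulative, measured from the first pre-frame), more than 1/3 of a raft
area outside the well, or 8 attempts.

The bundled actuator is a stochastic simulator: each actuation fully
clears the raft with probability `clear_prob(offset)` decreasing in the
aim error, otherwise removes a partial fraction and jolts the residue; it
is deterministic under a fixed seed and renders its frames with the same
renderer the tests use.

## What the synthetic scenes emulate — and what they do not

The generator renders: the quad lattice (200 μm rafts, 30 μm gaps, 100 μm
barriers, 530 μm pitch) with a smooth sinusoidal distortion field,
per-quad jitter and global rotation; a focus-invariant static background
texture attached to the array; dark PDMS (0.78) vs bright raft interiors
(1.00) with thin rim lines (0.90); a linear illumination ramp (10%) and
per-plane Gaussian sensor noise (2%); a rigid background/signal scan
misregistration (2.0, −1.5 μm, 0.10°); and cells drawn only inside the
ground-truth mask as ±25% speckle plus a 20% perimeter halo whose pattern
decorrelates with defocus over a 15 μm length (roughly half an objective
depth of focus), so the SDP contrast collapses when planes are spaced
only a few μm apart — mirroring the empirical finding that defocus
spacings above ~8 μm are needed. Colony coverage is drawn as exact
per-raft fractions, so coverage, class and area truth are known to pixel
precision.

Deliberately **not** modelled: physically accurate defocus optics (no PSF
convolution), fluorescence photophysics, cell-scale morphology (single
cells, mitotic rounding), media-chamber occlusion, tile stitching, and
hardware timing. Passing the synthetic-analog bounds therefore
demonstrates that the algorithms are implemented correctly and are robust
to the modelled nuisances (noise, shading, misregistration, distortion,
defocus spacing) at the published operating points; it does not certify
the published performance numbers on real microscopy, which depend on
optical effects the renderer leaves out. The synthetic background is also
cleaner than a real scan, so contrast-gain figures here overshoot the
hardware figure and are asserted only as a conservative floor (> 2-fold).

## Problem sizes and numerical choices

Batch fixtures use a reduced 8 × 8-quad array rendered at 3.25 μm/px
(a 2× binning of the reference 1.625 μm/px; ~1340² px per plane), the
package's chosen desk-scale operating point; the full 41 × 41 lattice is
used where the lattice itself is under test (indexing under 67% deletion),
and the defocus sweep uses a fixed 4 × 4 scene. The segmentation batch is
20 scenes × ~15 colonies; the classification/area batch reuses it
(≥ 200 colonies with truth radius well above the 25 μm reporting cut).

Other numerical choices worth knowing:

* Registration: the rotation grid (0.05° step, coarse-to-fine) is scored
  on 2×-binned images by the energy-normalized correlation peak —
  normalization removes the bias toward 0° that interpolation smoothing
  otherwise introduces — and the winning angle's translation is refined on
  the full-resolution images by a single-step upsampled DFT (1/20 px). One
  transform is estimated per stack, on the middle plane: planes are
  acquired without stage motion.
* Flat fields are estimated per plane (block mean at 256 px, smoothing at
  block resolution with linear-extrapolated edges, bilinear upsampling);
  the estimator reproduces smooth shading to ~0.2% and is idempotent to
  well under 1%.
* Otsu thresholds are computed by an inlined histogram routine that
  reproduces `EBImage::otsu` bin-for-bin (cross-checked in the tests) but
  accepts arbitrary valid-pixel vectors.
* Invalid pixels (resampled from outside the frame) propagate as `NA`,
  are excluded from all histograms, and count as background in masks.
* Degenerate inputs fail loudly: constant images cannot be registered,
  single-plane stacks have no SDP, non-positive images have no flat field,
  colonies requested outside the grid are rejected.

## Known limitations

* The greedy nearest-neighbour tour is a heuristic; it is asserted to beat
  a row-major scan in the many-target regime, not to be optimal.
* Coverage footprints assume rafts stay rigid squares on the fitted
  lattice; a grossly deformed array would need per-raft segmentation.
* The interpolation fallback for rows/columns with fewer than two anchors
  borrows the nearest anchors, which extrapolates; positions with no
  anchors in either direction are reported unresolvable rather than
  guessed.
* The release-frame classifier assumes transillumination polarity (cleared
  well brighter than raft material); reflected-light imaging would need
  the complementary convention.
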