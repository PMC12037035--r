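---
title: "Quantifying membrane protein organization and dynamics with memquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane protein organization and dynamics with memquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memquant)
```

## Scope and model

memquant quantifies how membrane proteins such as CD20 and CD70 are
organized and move at the B-cell surface, from multi-channel fluorescence
microscopy. It covers seven connected analyses: surface-cluster
segmentation and measurement, Pearson/Manders colocalization with Costes
auto-thresholding, FRAP recovery fitting, single-particle track analysis,
proximity-ligation-assay (PLA) dot counting, bead-based conversion of
fluorescence to molecule numbers, and immunological-synapse detection
with recruitment scoring (plus the micropatterned-stamp variant of the
recruitment question). Because the studies this mirrors quantified
patient- and donor-derived cells whose raw images are not deposited at
desk scale, every pipeline ships with a synthetic-scene generator whose
ground truth is exact; the tests are property-based against that truth.

## Cluster segmentation

`detect_clusters()` runs a fixed pipeline that mirrors the common Fiji
recipe: Gaussian smoothing (default sigma 1 px, unstated in the original
protocols), local-maxima detection, maxima-seeded watershed
("Find Maxima / segmented particles" semantics), a global Otsu threshold
with a percent offset, the logical AND of watershed segmentation and
threshold mask, binary hole filling, and 8-connected labeling with a
minimum size of 4 px (a noise guard, configurable).

Two details deserve explanation:

* **The percent offset.** "Otsu, 20%" is read as lowering the Otsu
  threshold by 20%. We apply the offset to the span above the image
  minimum, `min + 0.8 (T - min)`, which equals `0.8 T` for
  zero-background images but in addition makes cluster count and area
  exactly invariant under a constant intensity offset — a property the
  plain `0.8 T` rule does not have (the offset moves the threshold
  1:1 with the data). Both `otsu_offset` and plain `auto` modes exist
  because the original protocol used either depending on channel
  (20% for CD20, 30% for CD70, or the automatic value).
* **Watershed splits survive hole filling.** Hole filling floods the
  background with 8-connectivity, so one-pixel watershed lines that
  reach the blob boundary are not "holes" and are not re-filled; blobs
  with two seeded maxima stay split. Final labels additionally respect
  watershed basin identity, so a filled region spanning two basins
  yields two clusters.

## Colocalization

`pearson_coefficient()` is the sample correlation over the analysis mask
(whole image, or a cell mask when given; zero–zero pixels are retained,
the Coloc2 convention). `manders_coefficients()` computes
`M1 = sum(A | B > T_b) / sum(A)` and symmetrically `M2`, with the
threshold pair found by the Costes bisection: thresholds are constrained
to the channel regression line and lowered until the correlation of the
pixels below both thresholds is in `(-0.01, 0]`.

Numerical choices:

* The regression line is **reduced major-axis** (standardized)
  regression, not the plain major axis. RMA is equivariant under
  rescaling either channel, which is exactly what makes M1/M2 invariant
  under multiplication of a channel by a positive scalar; the plain
  major axis rotates nonlinearly under one-channel scaling and breaks
  that invariance (we verified this empirically before switching).
* The bisection stops when the interval shrinks below 1/4096 of the
  channel range (scale-free; the classical "1 intensity unit" rule
  assumes integer images) or after 64 halvings, whichever comes first.
* Thresholds are clamped into the observed intensity range; an
  unclamped line can place `T_b` below zero on anti-correlated images,
  which silently turns M1 into 1.
* A constant channel makes the regression degenerate; the function
  falls back to fixed (Otsu) thresholds with a warning.

## FRAP

`normalize_series()` implements the easyFRAP-style double normalization

\[
I_{norm}(t) = \frac{roi(t) - bg(t)}{cell(t) - bg(t)} \cdot
\frac{\overline{(cell - bg)}_{pre}}{\overline{(roi - bg)}_{pre}},
\]

which cancels both background and acquisition photobleaching (any
common exponential decay divides out exactly), and fixes the pre-bleach
mean at 1. `fit_recovery()` fits the single-exponential model
`I(t') = I0 + A (1 - e^{-t'/tau})` on post-bleach time. Rather than a
multi-start nonlinear optimizer, the two linear parameters are profiled
out by least squares and `tau` is found by one-dimensional optimization
of the profiled RSS over a wide log-spaced bracket — this converges
unattended for any finite input, which is why the `converged` flag is
almost always true and no restarts are needed. The mobile fraction uses
the fitted plateau, `A / (1 - I0)` (`plateau_method = "last_frames"`
reproduces the manual last-points convention); `t_half = tau * log(2)`
is a model identity, tested as such. The generator's `noise_sd` is
relative to the pre-bleach ROI signal so that `0.01` means "1% noise";
the acquisition-bleach rate is a free parameter because the magnitude in
the original movies is not stated.

## Single-particle tracking

`link_detections()` uses greedy mutual-nearest-neighbor linking with gap
bridging (max 2 missing frames by default) — a documented simplification
of LAP-style trackers that is adequate at low particle densities and is
permutation-invariant within frames. `msd_curve()` is the time-averaged
MSD; `classify_motion()` fits the log–log MSD exponent `alpha` in
sliding windows (lags 1..window/4, starting at lag 2 when the window
allows, to suppress the localization-error intercept) and labels windows
confined (`alpha < 0.6`), active (`alpha > 1.4`) or free. The thresholds
are configuration values validated against the synthetic generator only;
the original study did not define its criterion.

The trajectory generator performs per-frame two-state Markov switching
between reflected diffusion in a disc (confined) and diffusion plus
directed drift (active). Its defaults (D_confined 2e-4, D_active 1e-3
um^2/s, drift 0.1 um/s, 10 Hz, 10 nm localization error) were chosen to
reproduce the reported ~0.15 um/s average speed regime of CD20 at 10 Hz.
Note that the classification criterion is only meaningful when the
confined-state MSD saturates within a window: the "well-separated"
world used in the tests therefore uses stronger confinement
(D 5e-3 um^2/s in a 0.04 um radius) and a 0.5 um/s drift. With a
24-frame window each state switch costs up to ~a window of mislabeled
frames, which bounds achievable frame accuracy; at switch probability
0.005 this leaves comfortable headroom above the 90% requirement.

## PLA counting and molecule calibration

`count_pla_spots()` segments cells from the DAPI channel and dots from
the PLA channel (threshold, maxima-seeded watershed to split touching
dots, size window), then assigns each dot to the cell region containing
its centroid, falling back to the nearest cell centroid within 10 px,
else to `cell_id 0`. Cell segmentation uses a three-class (two-threshold)
Otsu: the synthetic DAPI channel renders a dim cell body with a brighter
nucleus (so footprints are segmentable from DAPI alone, which the
"containing region" rule needs), and the bright nuclei seed the
watershed. A merge heuristic decides whether the middle intensity class
is cell body or background (middle class counts as foreground when its
mean exceeds background by at least 15% of the bright-class contrast) —
this matters because plain Otsu on three-level images can land between
the two upper levels.

`calibrate_molecules()` fits the log10–log10 bead line (at least three
distinct positive-ABC populations), converts sample MFI to molecules,
and flags extrapolation outside the bead MFI range;
`molecules_per_cluster()` apportions a cell's molecule total across
clusters proportionally to integrated intensity, conserving the total
exactly.

## Synapse detection and recruitment

`detect_synapses()` thresholds CD3 at the `100 - p` percentile of the
cell foreground (default p = 1, the "top 1%" rule; the percentile is
computed over foreground, not the whole field, so it does not depend on
field-of-view size). Foreground again uses the three-class threshold,
because CD3 has three levels (background, T-cell body, contact
accumulation). Detection is made noise-robust by hysteresis: the
top-percentile pixels seed a region that grows to the connected area
above the level midway between foreground and percentile thresholds. On
noiseless scenes this reduces exactly to the percentile components; under
noise it recovers the full contact instead of a scatter of fragments —
without it, enriched contact pixels missed by the percentile threshold
can leak into the control regions and bias the out-of-synapse mean
upward (we observed exactly this failure before adding the growth step).
Candidates must contain at least `min_region_px` percentile pixels and
lie within `mhc2_adjacency_px` (default 3) of the MHC II mask, which
automates the original manual selection of B-cell contacts.

`score_recruitment()` compares the in-contact reporter mean with the
mean over five control regions congruent to the contact. Controls are
placed by seeded random **rotation** of the contact shape about the
partner-membrane centroid rather than translation: a translated arc
almost never fits a curved membrane, a rotated arc always does, and on
the synthetic annular membranes the rotation is exact. Placements must
put at least 80% of their pixels on the partner membrane, avoid the
contact and its 2-px dilation, and the out-of-synapse mean is computed
over the on-membrane pixels. Recruitment is `enrichment >= 150%`,
deliberately inclusive ("150% or higher"). `synapses_per_cell()` counts
MHC II+ and CD3+ regions and divides synapses by B cells;
`compare_groups()` aggregates per image — the experimental unit — and
applies a two-sided Mann–Whitney test (normal approximation, since
per-image recruited fractions are heavily tied).

When applying the detector to data whose contact area differs from 1% of
the CD3 foreground, `cd3_top_percent` should be matched to that
fraction; the scaled-down synthetic conjugate scenes used in the
acceptance experiment have ~7–9% contact fractions and are analyzed
with `cd3_top_percent` 5–7 for exactly this reason (the original 1% was
tuned to the original imagery the same way).

## The synthetic world, and what a green test does not establish

Generators build cells as discs, membranes as ~3-px annuli, PSFs as
isotropic Gaussians (sigma 0.1 um — the Airyscan regime with its 150 nm
resolution limit), and noise as additive Gaussian clipped at zero, not
Poisson. Analytic masks make the ground truth exact, which is what lets
brute-force oracles (pixel counting, mask means, double-loop MSD)
verify every recorded quantity. The generators do not emulate vectorial
PSFs, spectral bleed-through, intensity inhomogeneity, irregular cell
shapes, z-structure, or motion blur; a green suite therefore establishes
algorithmic correctness on idealized geometry, not robustness to every
real-microscope artifact. Sub-resolution organization is out of reach by
construction, as it is for the microscope.

Scales are chosen once and kept: 0.05 um/px for Airyscan-like cluster
and colocalization scenes, 0.1 um/px for multi-cell scenes, 5-um stamp
discs on a 10-um pitch, 10 Hz tracking. The headline
recruitment experiment is simulated at the spec's scaled-down size
(30 images per group, 10 conjugates per image, true recruited fractions
0.6 vs 0.25 with per-synapse enrichment ratios drawn away from the 1.5
threshold by at least 0.3) and completes its 100 seeded replicates in
about 4.5 minutes on one CPU; the B/T cell radii (1.6/1.3 um) were
reduced from the display defaults (3/2.5 um) purely to fit that budget.

## Degenerate inputs and determinism

Blank channels yield empty results, not errors; a constant channel makes
Pearson undefined (missing value with a warning); zero B cells make
synapses-per-B-cell missing; an empty stamp channel is an error. Every
generator takes an explicit seed and restores the caller's RNG state, so
identical seeds give bit-identical scenes and the CLI is reproducible
end to end with `--seed`. All label rasters round-trip exactly through
16-bit TIFF; scenes round-trip bit-identically through 64-bit-float
TIFF with JSON metadata (channel names, pixel size, frame interval) in
the ImageDescription tag.

## Known limitations

Greedy linking will swap identities at high particle densities; the
motion classifier has no explicit state model (an HMM would localize
switches better than sliding windows); Costes randomization p-values and
object-based colocalization are not implemented; the TIFF codec reads
only uncompressed single-sample images (no CZI/LIF); and 3D analysis is
out of scope throughout — quantification happens on the ventral-membrane
plane, as in the experiments this package mirrors.
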