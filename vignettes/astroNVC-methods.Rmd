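---
title: "Models and methods behind astroNVC"
author: "astroNVC authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind astroNVC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astroNVC)
```

astroNVC analyzes the data streams of an awake two-photon neurovascular
experiment: GCaMP6f calcium movies of barrel-cortex astrocytes, rhodamine
images of penetrating arterioles, capillary line scans, dual-channel
leakiness stacks, hippocampal field potentials, and Y-maze arm entries. This
vignette explains each model, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data module does and does not
emulate.

## Synthetic data as the test bed

No raw recordings ship with the package; every analysis module instead has a
generator that produces its input with machine-readable ground truth, so the
whole pipeline can be validated closed-loop. The generators encode the study
conditions the analyses are built for:

* **Calcium traces** (`simTraces`): 180 × 180 µm fields imaged around a 10
  min spontaneous baseline; traces at 10 Hz (the movie frame rate is a free
  parameter of the rig, so it is configurable), baseline fluorescence 100
  a.u., additive Gaussian noise of 2% of baseline (typical for ROI-averaged
  awake GCaMP at this magnification; a Poisson shot-noise mode is available
  behind `shotNoise`). Transients follow a double-exponential
  \((1-e^{-t/\tau_r})e^{-t/\tau_d}\), rescaled so the waveform maximum equals
  the requested amplitude; defaults \(\tau_r = 2\) s, \(\tau_d = 6\) s and
  amplitude 50 %ΔF/F are in the range of spontaneous astrocyte somatic
  transients. The kinetic model itself is a package choice: only the
  measured rise/decay quantities are constrained by the analysis, and a
  two-time-constant waveform maps directly onto them.
* **Astrocyte movies** (`simAstroMovie`): Gaussian-profile blobs whose area
  above half maximum equals the requested pixel area (for a 2-D Gaussian
  that area is \(2\pi\sigma^2\ln 2\)), on a flat background — the size
  convention the segmentation filter uses.
* **Kymographs** (`simKymograph`): dark streaks of Gaussian cross-section;
  the slope in px/line is exactly `velocity × 1000 / (pixelSize ×
  lineRate)`. Defaults emulate a 10 µm scan at 2000 Hz (0.1 µm pixels);
  streak density 0.1 per line, contrast 0.5.
* **Vessel series** (`simVesselSeries`): plateau dilation at 2 frames/s —
  exponential rise during a 10 s stimulus, exponential return — normalized
  so the noiseless maximum is exactly `baseline × (1 + dilation/100)`.
* **Field sweeps** (`simFieldSweeps`): stimulus artifact, a fiber volley
  proportional to the stimulus level, an EPSP whose linear falling-phase
  slope follows a Boltzmann sigmoid of FV amplitude, and a fast
  population-spike notch on the recovery phase at and above a set level.
* **Arm entries** (`simArmEntries`): with probability *p* the next arm
  differs from both previous arms, otherwise the previous arm is repeated.
  Under this rule each sliding triad is an alternation exactly when two
  independent *p*-events succeed, so the expected alternation fraction is
  *p*²; the generator returns that analytic value as ground truth.

What the generators do **not** emulate: optics (no PSF, no depth
attenuation), motion artifacts, neuropil contamination, bleaching,
hemodynamic coupling between modalities, or correlated physiological noise.
Passing the closed-loop suites therefore demonstrates that the estimators
are correct and well calibrated under their stated noise model — not that
they are robust to every artifact of real recordings.

## ROI segmentation

`detectRois` seeds regions at local intensity maxima of the time-averaged
movie and applies a 600–6000 px footprint filter. The sensitivity knob is a
single scalar: a seed must exceed `median(image) + sensitivity × mad(image)`
(default 5). Each seed grows over the 8-connected region above
`background + growFraction × (seed − background)` (default 0.5, i.e. half
maximum above background); pixels claimed by several seeds go to the nearest
seed, ties to the lower label. Because every level is relative to the
background median, segmentation is invariant to constant offsets, and
raising the sensitivity can only remove ROIs.

Two robustness choices matter in practice. The image is pre-smoothed with a
1 px Gaussian before seeding (for regions of ≥ 600 px this inflates the
half-maximum footprint by well under 1%), and a seed whose grown region
contains pixels more than twice its own height above background is discarded
as a shoulder of a brighter structure — otherwise noise maxima on the skirt
of a bright astrocyte spawn fragment ROIs. The manual morphology curation of
a human analyst is not modeled; the size filter plus these two rules stand
in for it. The footprint (not the area above half maximum of the underlying
object) is what the size filter sees. Centroids are intensity-weighted, in
0-based pixel coordinates scaled by the pixel size.

## Calcium events

`computeDff` normalizes to the mean over a pre-stimulus baseline window
(%ΔF/F). `detectEvents` thresholds at `baseline mean + kSd × SD` (default
`kSd = 2`) on a 0.5 s boxcar-smoothed trace, and treats each contiguous
supra-threshold excursion as an event per local peak, with four guards whose
defaults were set on the generator's conditions:

* excursions shorter than `minDuration` (default 1 s; the validation suites
  use 2 s) are noise — astrocyte transients last seconds;
* sub-threshold gaps shorter than `minSeparation` (1 s) do not terminate an
  event;
* a secondary peak needs a valley descending at least half way back to
  threshold (`valleyFrac`), and
* both the event amplitude and a secondary peak's prominence must exceed
  `minAmpSd` (default 4) raw-baseline SDs. The threshold rule stays at 2 SD;
  this separate gate exists because noise riding the seconds-long decay tail
  of a large transient re-crosses a 2 SD line routinely, while genuine
  transients at a workable SNR (≥ 5) clear 4 SD by construction.

Kinetics follow fixed, configurable definitions: amplitude relative to the
local pre-event baseline (median of the second before onset; the
global-baseline amplitude is also reported), rise time as the interpolated
10–90% interval of the ascending limb, decay time as the interpolated
peak-to-50% interval, flagged censored when the trace ends first. On a
linear ramp the rise time is exactly 0.8 of the ramp duration; on an
exponential the half-decay is exactly τ ln 2 — both closed forms are asserted
in the tests. For evoked analyses the air-puff convention is a 10 s stimulus
with a 30 s post window, both configurable.

## Astrocyte network statistic

Events are binarized on a 2 Hz raster over 60 s windows — 120 samples per
ROI, 240 per pair; a bin is occupied when any part of an event's
supra-threshold span intersects the half-open bin. The pair statistic is the
Pearson correlation of the two binary rows (the phi coefficient; the
estimator is a package choice) scaled by the pair's event occupancy:
`wcc = cc × (1-bins of row i + 1-bins of row j) / 240`. "Events per pair" is
read as the total event samples across both rows, which is the reading
consistent with the 240-sample per-pair denominator; a coincident-bins mode
is available behind a flag. Pairs enter the analysis only when `wcc > 0.02`
(strict); correlogram edges and distance summaries use `cc ∈ [0.4, 1]`; a
field of view is kept only when more than 100 ROIs per mm² participate in at
least one included pair (a flag switches the gate to counting pairs
instead). The three 60 s windows (baseline, stimulation, recovery) are
aligned to the air-puff onset with configurable offsets.

## Vessel dynamics

Lumen area is measured per frame by Otsu thresholding inside the vessel ROI
(scale-invariant by construction) and treated as the volume proxy; only 2-D
frames at 2 frames/s exist, so radius-based measures are derived from area
when needed. The baseline is the mean of the lowest ⌈0.05 n⌉ measurements —
a percentile floor rather than the raw minimum, so single-frame artifact
drops do not define the baseline; frames more than 5 SD below it are
excluded from kinetics. Maximal dilation is reported as `100 × max /
baseline` (≥ 100% reads as dilation; the ratio direction is configurable).
Rise and fall slopes are linear fits over the 20–80% amplitude segments on
each side of the peak. End-foot timing is the signed interval from the
vessel dilation peak to the end-foot calcium peak. Leakiness is the
FOV-mean rhodamine/EGFP ratio at 0/15/30/45/60 min, renormalized to the 0
min point, so it is exactly 1 at time zero and cancels any gain common to
both channels. Vessel width histograms use half-open 0.5 µm bins and
two-sample Kolmogorov–Smirnov comparison (asymptotic p).

## Radon velocimetry

Each 50 ms bin of the kymograph (100 lines at 2000 Hz; bins shorter than 8
lines are skipped) is masked to a centered disk so the projection support
does not depend on orientation, and projected at angles φ over (−89°, 89°)
in 1° steps; the projection coordinate is `x cos φ + t sin φ` in pixel/line
units, and the streak angle is the φ maximizing the variance of the per-bin
projection means. The estimate is refined by symmetric grid bisection to
0.05°: a deterministic rule (argmax, ties to the smaller |angle|) chosen
over golden-section search so that mirroring the kymograph in space negates
the estimated velocity *exactly*, not just approximately. Velocity is
`−tan φ × pixelSize × lineRate / 1000` mm/s, positive toward increasing
spatial index. Confidence is the max/mean variance contrast over the coarse
grid (bins below 1.5 are flagged and excluded from metrics); a best angle at
the grid edge flags the bin saturated (unresolvably fast). Estimates are
invariant to affine intensity transforms. The velocity trace is smoothed
with a centered 750 ms moving average (15 bins, edge-truncated), and
stimulus metrics report the maximum change from the pre-stimulus baseline
(as a fraction of baseline) and the time to maximum from stimulus onset.

## Field potentials

The fiber volley is the first local minimum below baseline − 3 noise SD
after the artifact settles; the EPSP is the deepest subsequent trough; its
slope is the regression over the 20–80% segment of the falling phase (the
slope window is a package definition — only "mV/ms" is inherent to the
measure). The population spike is detected on the EPSP recovery phase by
matched filtering: the sweep is detrended with a 2 ms boxcar, convolved with
a unit-energy negative Gaussian of the expected notch width (0.25 ms sigma),
and a PS is declared when the response dips below 4 robust noise units
(estimated from the pre-artifact baseline and the late tail run through the
same filter; a noiseless sweep uses a small floor relative to EPSP
amplitude). A plain second-derivative rule was rejected: on noiseless data
it has no scale and fires on any waveform curvature.

Both the FV-vs-stimulus curve and the EPSP-slope-vs-FV (synaptic strength)
curve are fit with the three-parameter Boltzmann sigmoid
\(y = y_{max} / (1 + e^{(x_{50} - x)/k})\) by Levenberg–Marquardt least
squares (initialization: `max = 1.1 × observed max`, `half = median(x)`,
`slope = range/4`); non-convergent or degenerate (zero-variance) fits are
flagged and the raw per-level measurements are always exported. The derived
parameter set takes maximal FV, half-maximal FV and curve slope from the FV
fit, maximal EPSP slope and slope factor from the synaptic fit (both the
Boltzmann slope factor and the fitted maximum are exported, since "curve
slope" can mean either), the maximal EPSP/FV ratio from the raw
measurements, and the EPSP slope at the first PS-bearing level. LTP
normalizes 0.033 Hz EPSP slopes to the pre-tetanus mean (×100) and averages
the final 10 min of the post period — 20 sweeps at that rate.

## Behavior

An alternation is a sliding window of three consecutive entries with three
distinct arms; overlapping triads all count, matching the `entries − 2`
denominator of `% alternation = alternations / (entries − 2) × 100`.
Consecutive re-entries into the same arm are retained as entries. The score
is invariant under relabeling of the arms and bounded in [0, 100].

## Problem sizes and validation scope

The validation suites run at desk scale: 200 seeded traces for detection
recovery, 300–400-line kymographs (6–8 bins) per velocity, 100 noisy
sigmoid replicates, 1000 random sequences against brute-force oracles.
Group-level statistics across animals and diet conditions are out of scope
by design: the package exports tidy per-unit tables, and inference is left
to external statistical software.
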