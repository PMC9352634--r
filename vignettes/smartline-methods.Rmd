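---
title: "Smart line scanning: trajectory design and line-recording processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smart line scanning: trajectory design and line-recording processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smartline)
```

## The problem

Conventional two-photon calcium imaging raster-scans the full field of
view (FOV), spending most of the dwell time on pixels that carry no
somatic signal. Smart line scanning (SLS) instead drives the galvos
along a single trajectory that visits only the pixels of the segmented
regions of interest (ROIs), optionally a surround region around each
ROI, and a small "reference box" rectangle scanned raster-like at the
end of each pass. One pass of the trajectory is one *line*; its
reciprocal duration is the trace sampling rate, typically an order of
magnitude above the frame rate of the raster movie the trajectory was
designed on.

The price of scanning a 1-D trajectory is that the usual 2-D processing
tools no longer apply: there is no frame to register, ROI pixels can
drift off the scanned path, and background and neuropil contamination
must be estimated from the few non-somatic pixels that are scanned.
This package implements both halves of that workflow: raster-side
utilities (registration, projections, SNR-driven pixel selection,
longitudinal segmentation alignment, dF/F0, deconvolution), the
trajectory designer, and the SLS processing pipeline, plus a synthetic
session generator that provides ground truth for every stage.

## Signal statistics

Two statistics are used throughout. The SNR of a trace $f(t)$ is

$$\mathrm{SNR}(f) = \frac{\max_t f - \mathrm{mean}(f_{25})}
                         {\mathrm{sd}(f_{25})},$$

where $f_{25}$ are all samples strictly below the 25th percentile of
the trace and sd is the population standard deviation: the
sub-percentile tail estimates the noise floor, so the ratio measures
peak transient amplitude in noise units. Percentiles are
linear-interpolation (R type 7) and "below" is strict; the choice is
recorded here because the oracles in the test suite must agree with it
exactly. Normalised fluorescence is

$$dF/F_0(t) = \frac{f(t) - F_0}{F_0}, \qquad
  F_0 = \mathrm{mean}(f_{50}),$$

with $f_{50}$ the samples strictly below the median. Both statistics
reject degenerate traces (constant, or empty tails) with typed errors
rather than returning infinities.

## Trajectory design

ROI visiting order is a travelling-salesman problem over ROI centroids.
The tour is closed — the trajectory is rescanned cyclically, so the
jump from the last ROI back to the first is physically traversed — and
solved approximately by a genetic algorithm: a population of 100 random
permutations evolved for 1000 generations; each generation the global
best is retained, the population is split into random groups of 4, and
each group's best member spawns four children (itself, a flip =
reversal of a random subsegment, a swap = exchange of two random
positions, and a slide = one-step rotation of the subsegment, all three
sharing the same random cut points). There is no crossover and no
elitism beyond the retained global best. `brute_force_tsp()` enumerates
the $(n-1)!/2$ distinct closed tours for $n \le 10$ and serves as the
exact oracle in the tests; on random 7-centroid instances the GA
virtually always attains the enumerated optimum.

Within a ROI the path is a greedy nearest-neighbour chain entered from
the last pixel of the previous ROI (the first ROI is entered at its own
centroid); each ROI's surround pixels are chained immediately after its
ROI pixels. The surround is the Euclidean dilation of the ROI footprint
by a configurable radius, minus every ROI's pixels; a pixel reached by
two dilations goes to the nearer ROI (ties to the lower id), so no
pixel is scanned twice. Reference-box pixels are appended last in
row-major order. Scanning more pixels lowers the line rate
(`effective_line_rate()`), which is the designer's central trade-off:
surrounds and a reference box buy robustness to motion at the cost of
sampling rate.

## SLS processing

**Pixel classification.** Against the reference segmentation, each
trajectory pixel's minimal Euclidean distance $d$ to each ROI maps to a
class per ROI: $d \in [0,1]$ ROI, $(1,2]$ outer ring, $(2,4]$ surround.
A pixel with a class for exactly one ROI keeps it; pixels claimed by
two or more ROIs are discarded; pixels farther than 4 px from every ROI
are background. Endpoint inclusion (closed on the right) and the
pixel-centre metric are conventions fixed here; the intervals
themselves are the tool's operating definition.

**Large-artefact detection.** Large motion artefacts push the imaged
cells off the trajectory entirely and cannot be corrected, only
cropped. Because no image exists to register, detection is functional:
pixel traces are mean-centred, reduced by PCA, and the first
component's score vector is fitted with an AR(2) model — the dynamics
class that describes calcium transients. The model is fitted once to
the whole score vector by least squares on the two lagged scores
(scores are centred, so no intercept). While the recording is
physiological the one-step prediction tracks the scores and their
Pearson correlation, computed in a trailing 10 s window, stays high; the
first line where it drops below 0.3 is the crop point and all later
lines are discarded. The window is trailing (it ends at the evaluated
line) and the series is evaluated from the first full window onward;
windows in which either series is constant get correlation 0, which is
conservative (they cannot demonstrate AR-consistency).

**Background subtraction.** Background-class pixels estimate the
global fluorescence fluctuation: their activity is reduced to a rank-1
PCA reconstruction (per-pixel means re-added, principal-component sign
fixed so the mean loading is non-negative), averaged across pixels into
a series $b(t)$, scaled by the contamination ratio 0.7 and subtracted
from every trajectory pixel; negatives are clipped to zero. The 0.7
ratio is the GCaMP literature's standard somatic contamination
estimate and is a config default, not a constant.

**Line-by-line motion correction.** Two strategies, chosen per
recording:

* *Reference box* (`correct_motion_refbox()`): the refbox pixels of
  each line are reshaped into a small image; the image sequence,
  optionally smoothed (and decimated) over a 0/1/10 s window, is
  registered rigidly to its first-frames template, and the negated
  correction is the tissue displacement per line (nearest assignment
  maps decimated shifts back to lines). Each ROI's reference footprint
  shifted by the rounded displacement is intersected with its pool
  (ROI + outer ring + surround trajectory pixels); shifted pixels that
  fall off the trajectory are dropped from that line's assignment
  rather than substituted.
* *SNR reassignment* (`correct_motion_snr()`): per ROI and line, the
  single-pixel SNR over the subsequent 10 s window is computed for every
  pool pixel; pixels are sorted by descending SNR (ties by (row, col))
  and the top $n$ pixels, $n$ the reference ROI pixel count, are
  assigned to the ROI for that line. The window is forward-looking and
  truncated at the recording end. This method needs visible transients
  inside most windows: for ROIs with long silent stretches the ranking
  degenerates to noise ordering and the assignment can wander into the
  surround, a limitation inherited from the method itself and visible
  in the synthetic sessions.

**Neuropil decontamination.** Locally, each ROI trace is the mean over
its assigned pixels minus 0.7 times the mean over its neuropil pixels
(its surround-class pixels, or, after reassignment, the per-line
unassigned pool), clipped at zero; a ROI with no neuropil pixels passes
through and is flagged in the provenance. Globally, per-ROI signals
(assigned + surround pixels) are reduced to a rank-1 PCA
reconstruction — interpretable as a global neuropil signal — which is
subtracted from each ROI's plain pixel trace.

**Pipeline.** `run_pipeline()` applies any subset of the steps in the
user's order (the two motion methods, and the two neuropil methods, are
mutually exclusive), classifies pixels first, and reports the change in
mean per-ROI SNR and mean pairwise correlation against raw traces over
the same lines. A good pipeline preserves or raises SNR while lowering
pairwise correlations; correlations that stay high usually mean shared
background/neuropil signal survived processing. Motion-only pipelines
do not remove shared signal and therefore should not lower
correlations appreciably — a property the acceptance suite checks on
synthetic sessions.

## The synthetic session generator

The generator emulates the kind of data this pipeline targets:
GCaMP6s-expressing somata in mouse cortex imaged at tens of Hz.

* Disk somata (radius 3 px, 29 pixels) with a smooth per-pixel gain,
  placed by rejection sampling with a minimum separation; baseline
  soma brightness 100 counts over a 100-count photon offset. The
  rendered soma extends ~1.5 px past the segmented rim with decaying
  gain — the point-spread function blurs somatic signal into adjacent
  pixels — so trajectory pixels just outside the footprint carry
  attenuated somatic signal, as they do in real data. The segmentation
  itself contains only the core disk.
* Poisson spikes filtered by the AR(2) kernel $(1.6, -0.64)$, whose
  impulse response is normalised so a single spike peaks at
  `spike_amplitude` dF/F. Defaults emulate bursty GCaMP6s events:
  sparse large transients rather than dense single-AP responses, which
  both matches awake-cortex data and exercises the SNR-reassignment
  method in its intended regime (every 10 s window contains transients).
* A spatially uniform background series and a smooth neuropil field
  with a shared slow component plus per-ROI jitter; both are slow
  smoothed Gaussian processes scaled linearly by their amplitudes. The
  defaults put the synthetic raw data in the contaminated regime (raw
  pairwise trace correlations of roughly 0.05-0.3) that background and
  neuropil subtraction exist to fix.
* Additive Gaussian noise (shot-noise stand-in) and rigid planar
  motion: a random-walk drift and/or an abrupt large shift, applied to
  the whole scene; within-line time is collapsed (all pixels of a line
  share a timestamp), matching the processing's line-atomic treatment.

The raster and SLS renderers share the scene composition and the RNG
draw order, so they agree *exactly* on trajectory coordinates under
identical motion and seeds — the invariant that lets every SLS test
validate against the raster ground truth. What the generator does not
model: optical PSF, depth-dependent scattering, Poisson photon
statistics, non-rigid deformation, and behaviourally structured
activity. Tests passing on these sessions therefore demonstrate
algorithmic correctness and directional behaviour, not performance on
any particular real preparation.

## Numerical choices

* Registration is FFT cross-correlation on demeaned images with
  quadratic subpixel peak refinement, capped at `max_shift`; refinement
  offsets below 1e-6 px are snapped to zero so a motion-free movie
  reports exactly (0, 0). The patch mode uses a 4x4 grid with 50%
  overlap and bilinear blending of patch shifts.
* Longitudinal alignment does an exhaustive grid search (shifts +/-20
  px step 1, angles +/-10 degrees step 0.5 by default) minimising the
  full-FOV zero-filled MSE; the search is evaluated exactly but
  accelerated with an integral image and padded FFT correlation.
* Deconvolution estimates AR coefficients by Yule-Walker on the
  demeaned trace autocovariance (order 1 below 2 Hz, else 2), rectifies
  the innovation to a non-negative activity and re-convolves it for the
  denoised trace. This is a deliberately simple estimator behind a
  stable interface; a constrained solver could be swapped in without
  touching callers.
* PCA rank-1 reconstructions always centre per series, re-add means,
  and fix the component sign so the mean loading is non-negative.
* All randomness flows from explicit seeds; every operation is
  reproducible byte-for-byte from (inputs, seed).

## Problem sizes

The test suite and the acceptance script run synthetic sessions of
roughly 30-45 s at 20 Hz line rate (600-900 lines) on 40x40 pixel
scenes with 4-6 ROIs, and artefact-detection batches of 100 seeded
recordings with ~100 trajectory pixels each. These sizes were chosen so
the full suite exercises every code path at realistic ratios (window
length vs recording length, pool size vs ROI size) while remaining
quick to run on a laptop.

## Known limitations

* The SNR-reassignment correction degrades for ROIs with long silent
  periods (noise-driven ranking), as discussed above.
* The refbox correction assumes rigid planar motion; it reports a
  single displacement per line.
* Yule-Walker deconvolution is not a constrained sparse solver; event
  amplitudes are rectified innovations, not calibrated spike counts.
* The float-TIFF writer stores values at float32 precision (integer
  count movies round-trip losslessly as 16-bit).
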