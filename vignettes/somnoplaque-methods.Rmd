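---
title: "Methods: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`somnoplaque` quantifies the readouts of sleep-and-amyloid experiments in
amyloidosis mouse models: vigilance states and their architecture from
EEG/EMG telemetry, state-specific spectral power, neuronal calcium from
ratiometric FRET imaging, amyloid plaque burden, microglia–plaque
clustering in 3-D, flow-cytometric phagocytosis, and behavior. This
vignette is the package's own account of the underlying models, the
tunable parameters that matter, and the numerical decisions taken where
the procedures in common use leave the details open.

## Sleep staging

### Model

Rodent vigilance states are scored per fixed-length epoch (10 s by
default) from two features: the EEG band-power profile and the EMG
root-mean-square. The classifier is a fixed decision cascade:

1. epochs with amplitude excursions or non-finite samples are `Artifact`
   and excluded from every downstream power average;
2. EMG RMS at or above the wake threshold ⇒ `Wake` — heightened muscle
   activity dominates whatever the spectrum shows;
3. theta/delta power ratio strictly above 3 ⇒ `REM` — theta
   predominance with muscle atonia;
4. everything else ⇒ `NREM`, the residual low-EMG, delta-dominant sleep
   class (optionally `Unscored` when the delta fraction is also low).

The ratio criterion (> 3) is the published rule; the bands are delta
0.5–4 Hz and theta 6–9 Hz. A second theta preset (4–8 Hz,
`theta_wide`) is shipped because both conventions appear in the rodent
sleep literature, sometimes within a single study; the 6–9 Hz band
drives the REM ratio here, and either can be used for band-power
reporting. Neither convention is declared "correct" — they are presets.

The classifier is stateless across epochs: no smoothing and no
contextual transition rules (e.g. forbidding Wake→REM), because the
scoring criteria themselves state none. Permuting epochs permutes labels
identically, which the tests assert.

### Thresholds

Commercial scoring modules do not publish their internal thresholds, so
`derive_thresholds()` computes documented substitutes from the data:

- **EMG wake threshold** — Otsu's criterion on log(EMG RMS) over
  artifact-free epochs. Muscle tone is strongly bimodal (wake vs.
  sleep), and the log transform makes the two clusters comparably wide.
  If the distribution is degenerate or the class separation is below
  0.5 natural-log units, a warning is raised and a configurable fallback
  (2× the median RMS by default) is used.
- **NREM delta fraction** — midpoint between the two Otsu class means of
  the per-epoch delta/total fraction. Only consulted in `Unscored`
  mode.
- Thresholds supplied explicitly are returned unchanged.

These derived thresholds are validated only against synthetic ground
truth; on real recordings they are a starting point, not a calibration.

Boundary conventions, fixed and tested: EMG uses `>=` (an epoch exactly
at the threshold is Wake); the REM ratio uses strict `>` (exactly 3 is
NREM); the artifact criterion is an absolute amplitude cutoff (400 µV
default), an operational stand-in for "epochs without artifact".

## Architecture metrics

A **bout** is a *maximal* run of at least two consecutive same-state
epochs (≥ 20 s at 10-s epochs); a four-epoch run is one bout, not two,
and single epochs contribute no bout. Artifact epochs break runs and
never form bouts, since they are excluded epochs. Two conventions were
open and are fixed as follows: a bout crossing the light/dark boundary
is assigned to the window containing its *start* epoch (simple and
deterministic), and the epoch's own phase is assigned from its start
time against the light schedule (07:00–19:00 default) rather than by
majority overlap. Epochs are record-aligned (tiling from the first
sample) rather than clock-aligned.

State minutes are integer epoch accounting — counts × epoch length / 60
— so states always partition the recording exactly and light + dark
totals equal the 24-h totals; empty cells report `NA` means, never zero.

## Spectral analysis

Per-epoch periodograms use a periodic Hann window without overlap and
without averaging across windows within an epoch. The normalisation
divides by the window energy `U = Σw²`, which makes white noise
spectrally unbiased and yields the Parseval identity

`Σ psd · Δf = Σ (w·x)² / U`

— i.e. the periodogram integrates to the windowed-signal energy
corrected for the Hann energy gain. The tests assert this identity to
1e-6 relative (it holds to machine precision).

Band intervals are half-open `[lo, hi)` so adjacent bands are disjoint
and a disjoint cover of the analysis range sums exactly to the total;
the common convention of writing shared endpoints (4 Hz in both delta
and theta) would double-count the boundary bin.

"Total power" is not defined by the scoring conventions; the package
normalises over 0.5–24 Hz by default — the widest band it reports
(beta ends at 24 Hz) — configurable up to just below Nyquist. State
spectra average the per-epoch periodograms of qualifying (state-matched,
artifact-free, window-matched) epochs first and normalise afterwards;
the alternative order (normalise each epoch, then average) weights
epochs equally regardless of amplitude and is deliberately not the
default. SWA is the 0.5–1 Hz sub-band of delta, so SWA ≤ delta always.

## Calcium (FRET)

Neurite ROIs are inputs (label images or the synthetic generator's
label plane) because such ROIs are drawn manually in practice. The
ratio is background-corrected per channel,
`R = (ȳ_YFP − bg_YFP)/(ȳ_CFP − bg_CFP)`; ROIs whose corrected CFP is
non-positive are excluded with a reason code instead of producing
division blow-ups. R is invariant to any common gain.

Conversion to concentration uses the Hill relation
`Ca = Kd ((R − Rmin)/(Rmax − R))^(1/n)`, strictly increasing on
(Rmin, Rmax), with `R = (Rmin+Rmax)/2 ⇒ Ca = Kd` exactly. Ratios at or
below Rmin saturate to 0 nM; ratios at or above Rmax are *censored*
(`NA` plus a flag), never an infinite value in a table. The calibration
constants (Kd, n, Rmin, Rmax) are sensor- and preparation-specific and
must come from a calibration experiment; the shipped
`yc36_synthetic_calibration()` profile (Kd 232 nM, n 1.7, Rmin 1.0,
Rmax 2.6) exists so examples run and is chosen to be plausible for a
cameleon-type sensor — under it a ratio of 1.79 maps to roughly 235 nM,
a convenient configuration sanity check, but it is not a measured
calibration.

**Overload** is `R > mean + 2·SD` of a control (nontransgenic)
population. The SD is the sample estimator (n−1) — the estimator is
never stated in practice and n−1 is the conventional default — and the
inequality is strict, so for Gaussian controls the expected
false-positive rate on fresh control draws is the one-sided 2-SD tail,
Φ(−2) ≈ 2.3 %, which the tests confirm by simulation. The threshold is
always computed from the supplied control data and recorded alongside
the results; published point values for such cutoffs are inconsistent
enough between a results text and a figure legend that hard-coding one
would be wrong. Histogram weighting is per-ROI (one neurite, one
count), not per-pixel.

Pseudocolor maps follow the HSV construction used for ratiometric
imaging: the ratio clamped to [Rmin, Rmax] supplies hue (blue→red by
default) at full saturation and the normalised reference image supplies
value, so zero-reference pixels are black whatever their ratio.

## Plaque segmentation

Maximum-intensity projection, then thresholding (Otsu on the projected
image by default, since the fixed thresholds used in image-analysis
practice are rarely reported; a fixed mode exists for reproducibility
runs), then connected components — 8-connectivity in 2-D,
26-connectivity in 3-D — with components below `min_size_px` (default
10) removed to suppress shot noise. Burden is
100 × plaque pixels / ROI pixels, with the ROI mask (or the whole
image) as denominator; sizes are reported in physical units. Counting is
additive over disjoint regions and monotone under the min-size filter,
both tested. Component labelling is cross-checked against an
independent queue-based flood fill on randomised disk images.

## Microglia

Distances are **exact**: each soma centroid's Euclidean distance to the
nearest plaque-positive voxel center, with anisotropic voxel scaling.
The coordinate convention places 1-based voxel `i` at
`(i−1)·voxel_size`, so a unit-voxel mask with a single voxel at index
(1, 4, 5) sits at (0 µm, 3 µm, 4 µm) and a soma at the origin is exactly
5 µm away. Whether a 3-D rendering tool measures centroid-to-surface or
sphere-edge-to-surface is generally not stated; centroid-to-surface is
used, and subtracting a soma radius recovers the other convention.
Plaque association uses the 25 µm radius inclusively (`<=`): a cell at
exactly 25 µm is associated, 25.1 µm is excluded. With no plaque voxels
all distances are infinite and flagged, not silently zero.

Soma detection is scale-space blob detection (anisotropic Gaussian
smoothing at the soma scale, default 4 µm, then 26-neighbourhood local
maxima above a relative threshold); voxel sizes are mandatory so
anisotropy can never be silently ignored. An externally supplied point
list is accepted verbatim.

**Process length** approximates filament tracing by geodesic centerline
extraction: foreground voxels form a 26-connected graph with physical
edge lengths; the soma anchors at the thickest voxel (peak of an
erosion-depth map); branches are extracted greedily — route the
geodesically farthest voxel to the current centerline through its
shortest path — while the residual distance exceeds
`max(5 µm, 2.5 × erosion depth)`. The 2.5 factor covers the gap between
the Chebyshev erosion depth and the Euclidean radius (up to √3) with
headroom, so a compact sphere yields ~0 length while thin processes are
traced tip-to-tip. The tracer is validated on synthetic rods (a 40 µm
rod reads 40 ± 2 µm; two rods of 30 and 20 µm from one soma read ~50 µm)
and is an approximation, stated as such: on real ramified microglia it
undercounts short terminal branchlets below the floor and can overcount
by a soma radius when a branch is routed through the soma.

## Flow cytometry

Gating is rectangular and manual (CD11b ≥ lower bound, CD45 within a
low window), matching the described strategy; no automated clustering.
Transforms (asinh with cofactor 150 by default, or log10) are strictly
monotone so gates commute with them. The Methoxy-positivity threshold is
**control-anchored**: the 99.5 % quantile (type-7, deterministic) of the
control sample's Methoxy distribution within the microglia gate. The
quantile level is the package's choice — the control-anchored procedure
is standard but the cutoff statistic is typically unstated — and it
fixes the design false-positive rate at 0.5 % on fresh control draws,
which the tests confirm. Positivity is strict (`>`), MFI is the median
on the untransformed scale, and empty gates yield `NA`, never zero.
Events are ingested from CSV; binary cytometry containers are out of
scope for the core.

## Behavior

Freezing: motion-index frames strictly below the (required, calibrated
upstream) threshold form runs; runs of at least `min_freeze_s` count.
The 1 s default is the conventional minimum-duration rule; setting it to
0 gives the pure-threshold reading. Alternation: sliding windows of
three consecutive entries, distinct-arm windows / (N − 2); immediate
re-entries are collapsed on ingest (logged), and results are invariant
under arm relabeling. Open field: distance is the summed Euclidean step
length; the center zone is the concentric square with half the arena
side (25 % of the area) — a convention, as zone definitions usually are
— and center + border time equals total time by construction.

## Synthetic generators: what they emulate, and what they do not

The generators reproduce the *statistical structure the analyses
assume*, not the biology:

- **Sleep**: a 3-state Markov chain over epochs; EEG per state is a sum
  of band-limited Gaussian noise components (SWA 0.5–1, delta 0.5–4,
  theta 6–9, beta 16–24 Hz) plus a 1/f background, amplitude-modulated
  per epoch, so traces are continuous across transitions; EMG is white
  noise with per-state amplitude. The default weights plant the
  canonical separations: NREM delta-dominant, REM theta/delta far above
  the criterion, wake EMG 5× sleep. A pure-tone mode supports analytic
  tests. Real EEG has within-state nonstationarity, spindles, and
  scorer-ambiguous transition epochs; none are modelled, so the ~100 %
  staging accuracy on synthetic data bounds the rule implementation's
  correctness, not real-world scoring agreement.
- **FRET**: curvilinear neurite strokes with disjoint pixel sets; CFP
  constant, YFP = ratio × CFP before noise, so noiseless ROI means equal
  the planted ratio exactly. The ratio mixture is two Gaussians with the
  overloaded mean 6 control-SDs up, 15 % overloaded by default. No
  spectral bleedthrough, no focal drift.
- **Plaques/microglia**: disks/balls with analytically known areas;
  soma points uniform or exponentially attracted to plaque surfaces;
  generator truth distances computed by a deliberately naive per-soma
  scan at generation time.
- **Flow**: log-normal mixtures at 10-fold separations with per-event
  labels and a paired control with zero planted positives. Real
  cytometry adds spillover, debris and doublets, all out of scope.
- **Behavior**: scheduled sub-threshold windows, no-immediate-repeat
  entry strings with tunable alternation propensity, reflected random
  walks.

All generators draw from one seeded stream per call and restore the
caller's RNG state; identical parameters and seed give bit-identical
outputs.

## Problem sizes and runtime choices

The test suite and the acceptance script exercise the pipeline at sizes
chosen to be statistically meaningful for each property: staging and
Markov recovery on 10,000 epochs (about 28 h of 10-s epochs) at
fs = 100 Hz; bout-oracle equivalence on 1,000 random hypnograms of
1,000 epochs; overload recovery on 20 seeds × 200 neurites; flow
recovery on 20 seeds × 50,000 events; geometry oracles on 100 random
images and 100 random 3-D configurations. The sampling rate for
synthetic telemetry defaults to 500 Hz (matching hardware whose analog
band extends to 200 Hz), but the large staging runs use 100 Hz — every
analysed band ends at 24 Hz, so a 50 Hz Nyquist is ample and the run
stays light. The spectral and EMG separations that define the study
conditions are identical at either rate.

## Known limitations

- The staging thresholds are derived substitutes; agreement with any
  specific commercial scorer on real data is untested and unknowable
  from synthetic data alone.
- The EDF reader/writer covers the minimal 2-channel, 1-s-record layout
  this package writes; EDF round trips are exact only to 16-bit
  quantization (CSV round trips are exact).
- Process length is a centerline approximation validated on rods, not a
  re-implementation of any commercial filament tracer.
- No FRET bleedthrough correction, no cytometry compensation, no
  longitudinal plaque registration, no video tracking — inputs are
  assumed preprocessed to the formats the package reads.
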