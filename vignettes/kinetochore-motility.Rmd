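---
title: "Modeling and quantifying kinetochore transport on dynamic microtubules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and quantifying kinetochore transport on dynamic microtubules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinetotrack)
```

## The system and the model

In reconstituted budding-yeast lysate assays, kinetochore particles bind the
lateral surface of dynamic microtubules, walk processively toward the plus
end, convert irreversibly to an end-on attachment when they reach the tip,
and then track the depolymerizing plus end back toward the minus end. The
behavior is read out on kymographs: position along the microtubule on one
axis, time on the other, with the motion appearing as sloped line segments
separated by horizontal pauses.

`kinetotrack` implements that picture as a continuous-time stochastic model
with four kinetochore states and a standard dynamic-instability model for
the free plus end:

* **Lateral phase.** With probability `p_motile` a kinetochore is motile;
  motile kinetochores alternate exponentially distributed *runs* (advancing
  toward the plus end at `v_run`, µm/min) and *pauses*. Non-motile
  kinetochores hold their position. Lateral motion is strictly plus-end
  directed; minus-end excursions of laterally bound kinetochores are
  negligible in this system and are not modeled.
* **Conversion.** When the plus end comes within one kymograph pixel
  (72.2 nm) of the kinetochore — because the kinetochore ran into the tip or
  a depolymerizing tip reached it — attachment converts to end-on,
  instantaneously and irreversibly.
* **Tip phase.** An end-on kinetochore is slaved to the plus end. The pair
  alternates *tip-tracking* (kinetochore-coupled depolymerization at
  `v_tip_track`, minus-end directed) and *tip pauses*. A kinetochore-bound
  plus end never regrows.
* **Free microtubule.** The plus end grows at `v_growth`, undergoes
  catastrophe as a Poisson process at frequency `f_cat`, shrinks at
  `v_depol_free` and is rescued at frequency `f_res`. The seed (position 0)
  is a stable template; a bare end that shrinks to the seed resumes growth.

All dwell times are exponential. The model only fixes occupancy fractions
(time moving versus paused), not dwell shapes, and the memoryless two-state
chain is the minimal model consistent with those fractions. Events are
sampled exactly in continuous time and discretized onto the camera frame
grid (default 5 s) at the very end, so dwell statistics carry no
frame-interval bias.

One modeling addition deserves emphasis: the preset carries a *free* rescue
frequency `f_res` even though the no-regrowth rule forbids rescue after
end-on conversion. Without free rescue, every catastrophe would march the
tip down onto the kinetochore and force conversion, driving the fraction of
kinetochores that reach the plus end toward 100% over a 30-minute movie at
any realistic catastrophe frequency. Free shrinking ends that are rescued
*above* the kinetochore restore growth; only the excursions that reach the
kinetochore convert it. The observed reach-the-end fractions (roughly 28%,
6% and 12% across the packaged conditions) are reproduced by the interplay
of `f_cat` and `f_res`.

## Genotype presets and calibration

`make_preset()` packages three conditions: `WT` (kinesin-8 positive),
`kip3_null` (motor deleted) and `kip3_dT_LZ` (tail-truncated motor,
dimerized through a leucine zipper), plus a `mif2_like` preset that scales
the run velocity by 0.71 for the slower inner-kinetochore proteins.

Two kinds of numbers live in a preset:

* **Measured quantities** are fixed at their published values and are never
  tuned: run velocities (0.56, 0.47, 0.76 µm/min), tip-tracking velocity
  (0.4 µm/min), free depolymerization velocity (0.82 µm/min), motile
  fractions (0.77, 0.28) and the add-back rescue probability (0.537).
* **Calibrated quantities** are model parameters the source measurements do
  not pin down: the four dwell-time means, `v_growth`, `f_cat` and `f_res`.
  These were calibrated, once, so that the *full* pipeline — simulate,
  render with noise and blinking, re-extract tracks from the images,
  segment, summarize — reproduces the published per-condition statistics
  (mean run velocity and run length, lateral and tip moving-time fractions,
  motile fraction, reach-the-end fraction) at the published cohort size of
  128 tracks. They are model values, not measurements, and are recorded in
  `inst/config/presets.yaml`.

Calibration must run through the full measurement chain because the
measurement is not unbiased at this resolution: runs shorter than the
detection floor are folded into pauses, pauses shorter than the 50 s slope
window are absorbed into runs, and both effects shift measured run lengths
and time fractions away from their generative values. For example, the `WT`
lateral dwells (45 s runs, 72 s pauses, a generative occupancy of 38%)
measure as a ~30% moving-time fraction after segmentation because part of
each run is consumed by the detection floor, and because the immobile 23%
of kinetochores contribute pure pause time to the pooled fraction.

Initial geometry: microtubules start at 2–6 µm (uniform), targeting the
physiological ~5 µm working length of the assay, and kinetochores land
uniformly over 10–90% of the initial length.

## Rendering

`render_kymograph()` converts a trajectory into a two-channel
distance × time raster at 72.2 nm pixels: the microtubule channel is a
uniform line of emitters from seed to tip, the kinetochore channel a point
emitter, both convolved with a 1D Gaussian PSF (σ = 150 nm, a
diffraction-limited TIRF value; the source does not state one, and only
relative geometry matters downstream). PSF integration is exact per pixel,
so summed intensity is conserved. Poisson shot noise (default) acts on
expected photon counts; the point emitter defaults to 300 photons/frame —
a kinetochore particle carries many fluorophore copies — over a background
of 5.

Blinking is an exponential on/off telegraph (default 20 s on / 10 s off)
applied to the red channel, matching the red fluorescent proteins that
blink in this assay while GFP does not. In the two-channel kymograph the
red channel is the microtubule; in colocalization fixtures the blinking
reference track plays that role.

What the renderer deliberately does not emulate: stage drift (inputs are
assumed registered), crossed or bundled microtubules (the corresponding QC
exclusion is a pass-through hook on synthetic data), camera gain and
chromatic shift, and the diffuse fast-moving population that the assay
could not resolve. Passing end-to-end tests on rendered data therefore
demonstrates correctness of the measurement chain under this idealized
imaging model, not robustness to every artifact of real movies.

## Track extraction and segmentation

`extract_track()` follows the intensity ridge with a windowed,
background-subtracted centroid (window centred on the in-window peak);
frames failing a peak *and* an integrated-mass visibility test are flagged
invisible and interpolated — this is what blinking gaps look like in real
kymographs. `extract_mt_end()` locates the plus end as the half-maximum
falling edge of the lightly smoothed line profile, with sub-pixel
interpolation. Both recover positions to well under half a pixel RMSE at
default noise.

`segment_track()` implements the quantification rules:

* **Slope threshold.** A centred 10-frame sliding window least-squares
  slope per frame; movement below one pixel per ten frames —
  72.2 nm / 50 s = 86.64 nm/min, conventionally quoted as 86.7 — is
  *paused*. The unrounded value is used internally; a slope exactly at
  threshold counts as moving.
* **Minimum span.** A movement must be detectable over one full window;
  shorter bursts fold into the surrounding pause. The spans of the smoothed
  labels decide detectability; refined segments may be shorter.
* **Boundary refinement.** Window smoothing smears every junction outward
  by up to half a window, which would bias run velocities down and moving
  time up. Each junction is therefore refined by a local two-piece
  least-squares changepoint search within ± one window. Refinement trades
  the strict threshold-monotonicity of the raw labels for unbiased
  boundaries; the jitter is bounded by the window, and `refine = FALSE`
  restores the strictly monotone raw-label estimator.
* **Conversion detection.** The first frame at which the track comes within
  one pixel of the plus end and stays there marks the lateral→end-on
  transition; afterwards only tip-tracking (minus-end) and tip-pause labels
  are possible.
* **Per-segment velocity** is the median of the window slopes evaluated
  inside the segment (falling back to a trimmed least-squares slope for
  segments not much longer than the window). The median mimics reading the
  slope off the steep stretch of a kymograph line and is robust to
  sub-resolution dwells buried inside a segment.

`summarize_track()` reports per-kinetochore statistics. Two interpretation
choices are made explicit:

* The per-kinetochore velocity is the duration-weighted mean over *run*
  segments only, since pause time is reported separately as a time
  fraction; a gross velocity (pauses included) is reported alongside.
* Tip-phase statistics stop once the microtubule has fully depolymerized to
  the seed (within two pixels of 0): the physical track ends there, and
  counting the clamped tail would fabricate tip-pause time.
* Tracks whose lateral phase is shorter than one slope window (for example
  near-immediate conversion) cannot be classified for lateral motility and
  are excluded from the motile-fraction denominator, while remaining in the
  reach-the-end denominator.

Cohort aggregation follows the conventions of the source figures:
velocities as mean ± SEM over tracks (tracks with no runs excluded from the
velocity mean, retained in the motile-fraction denominator), run lengths
pooled over runs, time fractions pooled over frames, histograms in 0.2-unit
bins with half-open `[k·w, (k+1)·w)` edges.

## Classifiers

**Colocalization** (`score_colocalization()`) is evaluated only on frames
where the blinking reference is visible. A frame colocalizes when both
signals are present within one pixel (0.0722 µm; the source scored
visually, so the distance criterion is ours). *Always* = every evaluated
frame; *partially* = an initial reference-alone prefix followed by
colocalization sustained to the end (≥ 90% of the remaining evaluated
frames, tolerating blink-induced gaps); everything else, including
colocalization that is later lost, maps to *never*.

**Spindle phenotype** (`classify_spindle()`) operationalizes "two distinct
peaks": local maxima with topographic prominence ≥ 25% of the
background-subtracted maximum and ≥ 0.5 µm separation. Exactly two peaks is
*bilobed*; one elongated signal or three-plus foci is *declustered*. Only
spindles 2–3 µm long are classified; others are rejected with an explicit
exclusion reason. Profiles are assumed bleach-corrected and
intensity-normalized.

## Statistics and orchestration

Group comparisons use the Kruskal–Wallis rank-sum test (via
`stats::kruskal.test`), the test used for every comparison in this
quantification; no multiple-testing correction is applied, matching the
source analysis. The degenerate all-tied case is defined as H = 0, p = 1.
`run_pipeline()` drives simulate → render → analyze → summarize per
genotype from a single validated configuration, fans the master seed out to
per-stage child seeds (`derive_seed()`) so stages can be rerun in
isolation, logs every defaulted parameter, and writes byte-reproducible
JSON/CSV summaries plus a plain-text report.

## Numerical choices and degenerate inputs

* Threshold comparisons use a relative guard of 1e−9 so the exact boundary
  case is classified as moving regardless of floating-point round-off.
* The end-on detector requires the within-one-pixel condition to hold for
  five consecutive frames (or to the end of the track) to reject
  noise-induced grazes.
* Rate changes at an epoch switch (the add-back experiment) redraw the
  remaining dwell from the new rates; for exponential dwells this is exact
  by memorylessness.
* A fully depolymerized pair sits at the seed in a terminal tip-pause;
  those frames are excluded from tip statistics (above).
* Empty cohorts, unknown presets, mismatched frame grids, sub-window
  tracks, probabilities outside [0, 1] and spindles outside the inclusion
  window all fail fast with specific messages.

## Problem sizes

The packaged demonstration and validation sizes are the study conditions:
cohorts of 128 trajectories, 30-minute movies at 5 s frames, two-replicate
phenotype counts of n = 50, and 200 seeded replicates of the 54-kinetochore
add-back experiment. End-to-end validation runs each 128-track cohort
through rendering and re-extraction in tens of seconds on a single CPU.
Where validation statistics are averaged, two independent cohorts are used
to damp the ±4-percentage-point binomial noise a single 128-track draw
carries on fraction-type statistics.

## Known limitations

* Exponential dwells put substantial mass below the 50 s detection window;
  the measured run-length distribution is therefore strongly
  detection-shaped, and generative dwells should not be read as measured
  dwell estimates.
* The tension-free, single-microtubule geometry says nothing about force
  coupling, multi-microtubule spindle geometry, or initial 3D capture.
* The tip-phase moving/paused split is modeled as a property of the
  kinetochore–tip couple; whether pausing originates with the microtubule
  or the kinetochore is not distinguishable from kymographs.
* Boundary refinement makes the moving-time fraction monotone in the
  threshold only up to one window of jitter per junction (exact
  monotonicity is available with `refine = FALSE`).
* The `kip3_dT_LZ` reach-the-end fraction runs a few points above its
  nominal value: the fast kinetochore keeps the tip gap small, so even
  frequent rescue leaves more converting excursions than in the other
  conditions.
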