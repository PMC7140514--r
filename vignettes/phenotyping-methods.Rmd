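---
title: "Phenotyping stem-cell-derived neuronal cultures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping stem-cell-derived neuronal cultures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurophenor)
```

`neurophenor` reduces the raw measurements of a standard neuronal
phenotyping battery — MEA voltage, GCaMP fluorescence, immunofluorescence
fields, oxygen-consumption time courses, Ct and ELISA tables — to the
figure-level quantities labs report, and ships a synthetic generator for
every modality so each reduction can be validated by recovering known
ground truth. This vignette records the models, the defaults and why
they were chosen, the numerical decisions, and what the synthetic tests
do and do not establish about real data.

## MEA analysis

### Filtering and noise

Extracellular voltage sampled at 12.5 kHz is band-passed to the spike
band with an order-3 Butterworth filter, 200–3000 Hz. The filter is
designed with `signal::butter` (bilinear transform with pre-warping), so
the single-pass magnitude response is −3 dB at both design cutoffs;
`filter_band_edges()` verifies this from the response itself. The filter
is applied forward–backward (`filtfilt`), giving zero phase distortion
so spike peak times are not shifted; the effective amplitude response is
then the square of the designed one, which does not move the peak
location and is irrelevant to threshold crossings expressed in units of
the *post-filter* noise SD. The order is a parameter; 3 is a common
hardware default and makes the pass band flat to < 1 % at 1 kHz.

The baseline noise SD is estimated per electrode with the robust median
estimator `sigma = median(|v|)/0.6745`, which is insensitive to the few
per-mille of samples occupied by spikes; a plain SD over a
caller-designated spike-free interval is available when a clean baseline
is known. On 60 s of unit Gaussian noise the estimator is accurate to
about 1 %.

### Spike detection

A spike is called at each positive excursion whose peak strictly exceeds
`threshold_sd x sigma`, with `threshold_sd = 6` by default. The literal
"+" polarity is respected (positive deflections only); a both-polarity
mode exists for hardware that thresholds symmetrically. After each
detection, crossings are suppressed for a 1 ms dead time so one biphasic
waveform cannot be counted twice; within a dead-time window the first
peak wins. Spike time is the peak sample divided by the sampling rate.
Two spikes closer than the dead time are physically one superposed
waveform in the voltage domain, so voltage-level analyses are compared
against ground truth collapsed to that resolution.

### Activity, bursts, network bursts

All three classifications are strict inequalities, which the test suite
probes at their exact boundaries:

- an electrode is **active** when its whole-recording average exceeds
  5 spikes/min (a 5-min recording with 25 spikes is inactive, 26 is
  active);
- a **single-electrode burst** is a fixed, non-overlapping 100 ms window
  holding more than 5 spikes; windows are counted individually, so two
  adjacent qualifying windows are two bursts. Fixed binning was chosen
  because the burst count is defined as a *count of windows*; a
  sliding-window mode (windows anchored at spikes, merged when
  overlapping) is provided for comparison but is not the default;
- a **network burst** is a 100 ms window in which more than 50 spikes
  occur simultaneously on at least `ceiling(0.35 x N)` of the well's `N`
  electrodes (6 of 16). The ceiling reading is the only way to put "35 %
  of the electrodes" on an integer electrode count without calling a
  burst below the stated fraction.

Burst and network-burst calling are verified against independent
brute-force bin-count oracles on 1000 random spike-train sets, and all
three counts are monotone in their thresholds by construction.

### The MEA generator

`simulate_spike_trains()` superposes, per electrode, a homogeneous
Poisson background, burst epochs (Poisson epoch starts; ~80 Hz firing
inside a 300 ms epoch), and well-wide network events: 100 ms epochs of
~700 Hz firing implanted simultaneously on a fixed electrode subset.
Network-event onsets are snapped to the 100 ms analysis grid so each
implanted event occupies a single analysis window and exact recovery at
zero background is a meaningful test. `simulate_mea_recording()` adds
Gaussian electrode noise and places a biphasic 1 ms waveform at each
spike time. The waveform is pre-scaled so its *post-filter* peak equals
the configured amplitude, and `filter_noise_gain()` converts the raw
noise SD to its post-filter value, so the detector-domain SNR is exact:
the recovery suite runs at post-filter SNR 8, where spike-time F1
exceeds 0.95 (the residual misses are the ~2 % of peaks whose local
noise pushes an 8-sigma waveform under the 6-sigma threshold, plus
sub-dead-time collisions). Defaults mirror the acquisition setting the
package targets: 16 electrodes/well, 12.5 kHz, 5-minute recordings.

What the generator does not emulate: real extracellular waveform
diversity (units, amplitude drift), electrode cross-talk, and
non-stationary noise. Passing recovery tests therefore demonstrates the
correctness of the reduction chain, not robustness to every artefact of
real recordings.

## Calcium imaging

Raw per-ROI traces follow `F = F0 + events (x) kernel − bleach + noise`,
with a double-exponential kernel (rise 0.2 s, decay 1.5 s, normalised to
unit peak) and a linear photobleach ramp. Defaults: 5000 frames at
31.5 ms/frame, F0 = 100 a.u., event amplitude 30 a.u. (single-event
ΔF/F peak 0.3).

**Bleach correction.** The correction computes the first-minus-last
frame difference and removes the straight line it defines, re-anchored
at F(0): a pure linear decay becomes exactly constant. Subtracting the
difference as a scalar (the literal reading) cannot flatten a ramp, so
the ramp interpretation is the default and the scalar mode is retained
only for comparison. The anchor choice has a known, documented bias:
events near the last frame leak a term `(K(0) − K(N)) x t/N` into the
corrected trace; the tests assert this closed form exactly.

**ΔF/F and ΔFmax.** `ΔF/F = (F − F0)/F0` with F0 the frame-0 intensity;
ROIs with `F0 <= 0` are flagged invalid and excluded from summaries.
ΔFmax defaults to `max(ΔF/F) − min(ΔF/F)` (the "largest change" of the
trace); a max-only mode exists because the phrase is ambiguous, and the
0.01 positivity threshold applies to whichever mode is configured. The
strict `> 0.01` boundary is probed directly (0.010 is negative, 0.011
positive).

A practical consequence the defaults respect: a range-based ΔFmax on `n`
noisy frames concentrates around `~2 sqrt(2 log n)` times the per-frame
noise SD, so a 0.01 threshold presumes trace noise well under 0.5 % of
F0 (high-sensitivity indicator + EMCCD territory). The generator's
default noise (0.1 a.u. on F0 = 100) keeps the silent-ROI null well
below threshold; event-bearing ROIs carry at least one transient and
events stay a few frames clear of the trace end so every event has a
visible onset.

**Synchrony.** The synchrony index is the mean pairwise Pearson
correlation of ΔF/F across spike-positive ROIs, clipped to [0, 1]. It is
1 for identical traces, ~0 for independent noise, and strictly larger
for shared event trains than for independent ones at matched rates.

## High-content imaging

### Nuclear tracing and expansion

Nuclei are segmented from the Hoechst channel by Otsu threshold, hole
filling, and watershed on the distance transform. A candidate is traced
when its area strictly exceeds 50 µm² *and* its mean intensity stays
below the pyknotic brightness threshold. No brightness cutoff is
published for the commercial pipeline; the package uses twice the field
median nuclear intensity, which cleanly separates the generator's
pyknotic nuclei (rendered ~2.5x brighter and below the area cutoff) and
is configurable.

"Expanded by 50 %" is read as +50 % *area* (not radius): each traced
nucleus grows by claiming its nearest background pixels — nearest-
nucleus assignment makes the growth label-competitive, so neighbouring
regions can never overlap or double-count cytoplasm — until the region
reaches 1.5x its nuclear area (to within one pixel; the measured gain on
an isolated disc is 50.0 %). A radius mode is available. Marker
positivity per region uses mean intensity above background mean + 3 SD
(background = pixels outside all regions); fractions follow the
population conventions Tubb3+/Ho over all traced cells and MAP2+, NeuN+,
CellROX+ among Tubb3+ cells.

### Neurite length and synaptic area

The Tubb3 channel is binarised (median + 3xMAD background rule, Otsu
optional), cell bodies are removed by a disc opening wider than any
neurite, small components are discarded, and the remaining processes are
thinned with the Guo–Hall two-subiteration algorithm. Guo–Hall was
chosen over Zhang–Suen because the latter leaves two-pixel-wide diagonal
staircases, which inflate path length by up to ~50 %; a final pass also
deletes redundant staircase corner pixels so the skeleton is a minimal
8-connected path. Length is the chamfer sum over skeleton links with
minimax weights 0.960 (orthogonal) and 1.358 (diagonal), which bound the
straight-line error to about ±4 % at any orientation — the plain
(1, sqrt(2)) weights err by +8 % at 22.5°. End effects (thinning eats
1–2 px per end; the rendered line caps add a similar amount) roughly
cancel; rendered-field recovery is within 5 % over random orientations.

Synaptic area binarises the Synapsin-I or PSD95 channel, intersects it
with the Tubb3 mask, and divides the intersection area (µm²) by the
total neurite length (µm). The generator records the rendered punctum
area overlapping Tubb3 as ground truth, so the recovery test is exact up
to binarisation noise; the metric doubles with punctum count and is zero
for puncta placed away from any Tubb3 signal.

The renderer places non-overlapping cells by rejection sampling (a field
too crowded to place errors out after bounded retries), draws neurites
as two-segment polylines from soma edges along paths that avoid other
somata (a neurite with no clear path is skipped and excluded from
ground truth), and keeps puncta disjoint. It does not emulate uneven
illumination, out-of-focus light, touching nuclei clusters, or true
synapse morphology; recovery results certify the measurement chain, not
segmentation robustness on difficult real fields.

## Metabolic flux

For each well the mitochondrial stress-test reductions are applied to a
12-measurement profile (3 per phase: baseline, oligomycin, FCCP,
rotenone/antimycin A): non-mitochondrial respiration is the rot/AA-phase
aggregate (mean by default; the min-of-phase convention is an option),
basal OCR is the *third baseline measurement* minus non-mitochondrial
respiration (exactly as defined, not the baseline mean), maximal OCR is
the FCCP-phase aggregate minus non-mitochondrial respiration, and spare
respiratory capacity is the dimensionless ratio maximal/basal (a x100
display mode exists). Basal ≤ 0 yields an undefined (NA) spare ratio
rather than a misleading number. Basal and maximal are reported per 1000
Hoechst⁺ cells after normalisation; the spare ratio is scale-free and
untouched. All metrics are invariant to an additive OCR offset, and the
noise-free profile reproduces the closed forms exactly.

## Molecular assays

ΔΔCt: per sample, `ΔCt = Ct(gene) − Ct(ActB)`; replicate ΔCt values are
averaged per condition before differencing (`ΔΔCt = mean ΔCt(cond) −
mean ΔCt(ref)`), amplification efficiency is fixed at 2 (the comparative
method's assumption; no standard-curve correction), and the outputs are
−ΔΔCt (the heatmap value; higher expression ⇒ larger −ΔΔCt; the
reference condition column is identically 0) and fold = 2^−ΔΔCt. The
generator constructs Ct tables whose fold changes invert exactly at zero
noise, and the round trip is tested as identical.

ELISA: Aβ concentrations are divided by culture protein (pg/µg); the
Aβ42/40 ratio is computed on raw concentrations and is therefore
invariant to the protein normalisation. Non-positive protein flags the
row invalid; the ratio is defined only where Aβ40 > 0.

## Group statistics

- `t_test()`: two-sided equal-variance Student's t (Welch behind a
  flag).
- `tukey_hsd()`: all-pairs Tukey–Kramer using `stats::ptukey`; the
  studentized-range p is already family-wise.
- `dunnett_test()`: many-to-one contrasts against a designated control.
  The family-wise adjusted p is `P(max|T| >= |t_i|)` under the joint
  multivariate-t distribution with the balanced-with-control correlation
  `rho_ij = sqrt(n_i n_j / ((n_i+n_0)(n_j+n_0)))`, approximated by
  seeded Monte Carlo with 1e5 draws by default. Monte Carlo was chosen
  over quadrature for transparency and seed-determinism; the 95 %
  quantile agrees with the multivariate-t quadrature value to four
  significant figures, and the tests cross-check adjusted p-values
  against `multcomp::glht`.

Null calibration over 10000 (t) and 5000 (Tukey, Dunnett) simulated
experiments at n = 4 per group holds the empirical type-I/family-wise
error inside [0.04, 0.06] at α = 0.05. Stars follow the usual figure
convention (*, **, *** at 0.05, 0.01, 0.001).

## Problem sizes, determinism, degenerate inputs

The validation suite runs at sizes chosen to make its statistical bands
meaningful on a laptop-class machine: a 16-electrode, 60 s recording at
post-filter SNR 8 for spike recovery; 1000 random trains for oracle
equivalence; 400 ROIs for the calcium fraction; a 1500x1500 px field of
500 cells for image recovery; 5000–10000 null simulations for the test
calibrations. Every simulator draws all randomness under its config seed
(`withr::with_seed`, leaving the caller's RNG untouched), so identical
configs give byte-identical outputs, including the end-to-end
`run_virtual_experiment()` bundle and its manifest hashes.

Undefined quantities are reported as NA sentinels, never as zero: the
mean firing rate of an empty active set, fractions with zero
denominators, the spare ratio at basal ≤ 0, dispersion at n < 2, and the
synchrony index below two active ROIs. Classification boundaries are
strict inequalities throughout, and the acceptance script recovers each
one operationally (by probing the classifier on a grid) rather than
restating it.

## Known limitations

- Spike detection is threshold-based; no spike sorting, and overlapping
  units or sub-dead-time doublets merge into single detections.
- The bleach model matches the first-minus-last linear correction; real
  exponential bleaching is only partially removed (an exponential
  generator mode exists for robustness checks).
- ROI masks are inputs; automatic ROI segmentation from movies is out of
  scope.
- The image pipeline assumes reasonably separated nuclei; heavily
  clumped fields will under-segment regardless of the watershed step.
- Dunnett p-values carry Monte Carlo error ~1/sqrt(draws); raise
  `n_draws` for p-values near a decision boundary.
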