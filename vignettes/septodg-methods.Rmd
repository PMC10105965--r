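---
title: "septodg: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{septodg: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(septodg)
```

This vignette is the package's account of its science: what each analysis
assumes, which tunable parameters matter and why their defaults are what
they are, what the synthetic-data generators do and do not emulate, and the
numerical choices a maintainer would want written down. It states no
empirical result that the test suite does not itself compute.

## 1. Photometry: ΔF/F and calcium events

**Model.** Bulk fluorescence from a genetically targeted population,
sampled at 10 Hz. ΔF/F = (F − F0)/F0 with F0 the *median of the whole
session*; the event threshold is 3 × the sample SD of the full-session
ΔF/F. Both follow the acquisition convention the pipeline reimplements,
and both make every downstream statistic invariant under multiplicative
rescaling of raw fluorescence (a property test enforces this). No baseline
window is specified by that convention, so SD is whole-session; no
detrending or low-pass filtering is applied by default.

**Events.** "Calcium activity events" is ambiguous between per-sample
exceedances and excursions. We implement contiguous suprathreshold
excursions — they match transient physiology — with two refinements:

* *Minimum duration* 0.2 s (2 samples at 10 Hz): rejects single-sample
  noise spikes (P ≈ 1.3 × 10⁻³ per sample at 3 SD would otherwise
  produce ~8 spurious events per 10-min session).
* *Gap merging* (`min_gap_s = 0.2`): sub-threshold dips shorter than
  0.2 s between runs are merged before the duration filter. A transient
  with ~0.4 s decay cannot terminate and re-initiate within 200 ms; without
  merging, noise dips on the decay tail split single transients into
  doubles (we observed +1 to +3 spurious events per session). Setting
  `min_gap_s = 0` restores bare maximal runs.

Per-sample suprathreshold fraction, suprathreshold area (AUC), count and
rate are all reported, so group comparisons can run on either readout
("cumulative activity" is not pinned down to one of them by the source
convention; we compute both).

**Detection-limit note.** With GCaMP6f-like kinetics (rise 0.1 s, decay
0.4 s) at 10 Hz, a transient whose peak is exactly 5 × the noise SD has its
second-highest sample near 3.9 SD — right at the 3 SD threshold once the
threshold includes transient variance. Recovery there is inherently
marginal (~50%) regardless of implementation; the recovery tests therefore
use peaks at 8 × noise SD (still "≥ 5 ×"), where recovery is complete, and
this boundary behaviour is the reason, not test convenience.

**Motion control.** The mCherry channel carries the same motion waveform as
the GCaMP channel but no activity. `motion_correct()` fits
`dff_gcamp ~ a · dff_mcherry + b` by OLS and subtracts the predicted
component; regression is the minimal defensible reading of "used for motion
control", and the correction is switchable. One subtlety: OLS on the *raw*
control channel is attenuated by the channel's shot noise
(errors-in-variables), leaving ~half the artifact in place at realistic
control-channel SNR. Because motion is slow, smoothing the regressor (1 s
moving average; `smooth_s`) removes the attenuation without touching the
artifact. The bare contract default stays plain OLS; the session wrapper
`analyze_photometry_session()` uses the 1-s smoothing.

## 2. Peri-event analysis and MS–DG coupling

Behavior (20 Hz) is snapped onto the photometry grid (nearest sample,
error ≤ 50 ms). The peri-event window defaults to (−2 s, +4 s) — the
source convention says only "pre, during, and post" — with an inclusive
time grid (61 samples at 10 Hz). Heat-map rows are min–max scaled
(mirroring "scaled heat maps"); statistics always use unscaled values, and
a property test asserts scaling can never change a coupling result.

The per-bout response is the in-bout mean ΔF/F minus the pre-window mean
(baseline subtraction removes slow drift; the raw mean is also available).
Coupling is the two-tailed Pearson correlation across bouts, with explicit
undefined-result flags for zero-variance input.

**Generator design (revised during development, ledgered).** Two
structural choices matter for recovery fidelity and were corrected after
their failure modes were understood:

* Bout-locked activity is *sustained*: transients every 1 s from bout
  onset to offset, all scaled by the bout's amplitude. A single
  onset-locked 0.4-s transient averaged over a 3-s bout dilutes the signal
  ~6-fold and attenuates recovered coupling by ~0.05; sustained elevation
  matches peri-event averages that stay raised throughout exploration.
* Scripted bouts keep a 4-s guard between offset and the next onset, so
  one bout's calcium decay never contaminates the next bout's pre-onset
  baseline. With a 2-s guard the shared contamination inflated
  null-coupling r by ~0.1–0.2.

Per-bout (DG, MS) amplitudes are bivariate normal with correlation ρ
(positivity floor binds only beyond ~3 SD). Heavier-tailed amplitude
models (e.g. lognormal) were rejected because they inflate the sampling
variance of Pearson r.

## 3. Novel place recognition

A frame is exploratory toward an object iff the head is within 2 cm
(centre-to-centre minus a configurable object radius, default 0) *and* the
head direction is within θ = 45° of the bearing to the object — the
orientation cone is a field convention; the source states orientation
without an angle. Bouts are runs ≥ 0.25 s. The analysis clock starts when
the animal first leaves the corner zones (10-cm squares, configurable);
frames before that are ignored. The recognition score is
(t_novel − t_familiar)/(t_novel + t_familiar); zero total exploration
yields an exclusion flag, never a value — mirroring animals disqualified
for not exploring. Property tests assert antisymmetry under label swap,
invariance under time rescaling, and bout-detection invariance under rigid
rotation of the arena.

## 4. Electrophysiology

**QC.** Cells whose access resistance changes by more than 20% between
checkpoints are excluded (strictly greater: exactly 20% passes, a
documented boundary convention).

**sIPSC detection** (the acquisition-software algorithm is not public, so
this detector is the package's own, parameter-transparent design): 1 kHz
windowed-sinc low-pass; running-median baseline (0.2 s); noise SD as a
robust MAD estimate of the raw-minus-baseline residual — estimated on the
*raw* trace so the threshold is anchored to physical noise rather than to
the filtered trace's reduced variance; events where the inward deviation
exceeds 3.5 × noise SD; one event per excursion with a 5 ms minimum
inter-event interval and a re-arm rule (the deviation must fall below half
the threshold before a new event can be declared) so threshold
re-crossings on the 8 ms decay tail are not double-counted. Amplitudes are
positive magnitudes (inward currents at −65 mV holding with a CsCl
internal). Absolute event counts are not comparable to any specific
acquisition software; within-pipeline contrasts are the supported use.

**Opto epochs.** 20-s light epochs once per 60-s cycle; per cell,
frequency and amplitude are computed in the 20-s pre-light and light
windows of each cycle, averaged across cycles, and compared by paired
two-tailed t-tests. Events exactly at an epoch onset belong to the light
window.

**Intrinsic properties.** R = ΔV_ss/ΔI from the −20 pA, 200 ms pulse with
steady state over the last 25% (≥ 5 τ for typical granule cells); τ from a
log-linear fit refined by nonlinear least squares (the refinement matters
under noise, where the log transform is unstable); C = τ/R (the
amplifier-reported capacitance convention would differ; τ/R is what the
package computes). Spikes are upward 0 mV crossings with a 2 ms
refractory; AP threshold is the voltage just before dV/dt first exceeds
20 mV/ms. The LIF generator places its firing threshold midway between
two ladder steps, so "rheobase 110 pA" yields firing first at the 120 pA
step — the measured rheobase is defined as the first firing ladder step.

**Group statistics.** Per-cell means by unpaired two-tailed Student
t-tests; pooled amplitude and inter-event-interval CDFs by two-sample KS
(asymptotic, ties-tolerant); F–I tables by two-way ANOVA with Type II sums
of squares, chosen because genotype cell counts are unbalanced; Type II is
computed by nested model comparisons and verified against `aov` on
balanced designs where Type I equals Type II.

## 5. Tracing quantification

All arrays are (z, y, x), voxel centres at (i − 0.5) × voxel size, masks
half-open boxes; 26-connectivity in 3D, 8 in 2D.

The commercial surface-reconstruction step is replaced by a defined,
testable procedure that preserves the same observables: Otsu threshold
(one logged threshold per batch so genotypes are treated identically) →
connected components inside the extruded hilus ROI → per-object voxel
volumes summed → normalised by hilar ROI volume and MS starter-cell
density (cells / (MS ROI area × 40 µm)). The component labeler is verified
against an independent flood-fill oracle on 32³ fixtures, and capsule
voxelization against analytic cylinder-plus-caps volumes at two voxel
sizes.

Retrograde maps: per-region thresholded mCherry area summed over sampled
sections (every 6th section, 40 µm; no interpolation between sections),
divided by starter area — the area-based denominator; a count-based
variant is available through `count_cells()`. Somata are blobs split by
distance-transform peaks with nearest-peak assignment (a compact stand-in
for marker-based watershed, equivalent for near-circular somata; two
spheres touching at one voxel resolve as two — a documented convention). A
soma is GABA⁺ iff its footprint's mean GABA intensity exceeds the GABA
channel's Otsu threshold; a constant (empty) GABA channel yields fraction
0, no detectable somata yield an undefined fraction.

## 6. Synthetic cohort: what it emulates, and what it does not

The generators emulate the *statistical structure the analyses assume*:
Poisson event trains with genotype-dependent rates (WT 4/min vs AD 8/min
home-cage, encoding the DG-hyperactivity direction at 2×), double-
exponential GCaMP6f-like transients (0.1/0.4 s; kinetics are free
parameters, not claims), shared motion artifacts, bounded-random-walk
arena tracks with scripted ground-truth bouts, Poisson sIPSC trains with
lognormal amplitudes (log 40 pA, σ 0.4) and epoch modulation, RC + LIF
membrane responses (R 150 MΩ, τ 20 ms, RMP −70 mV, rheobase 110 pA; AD
overrides 200 MΩ / 150 pA encode increased membrane resistance and reduced
excitability), and labeled volumes with capsule processes and disk/sphere
somata (co-localization fraction 0.64 anchors the reported 64% MS GABA⁺
input fraction; AD process count 2× WT encodes the late-stage density
direction). One global seed drives everything; each stage derives a child
seed deterministically, so stages can be re-run in isolation and all
generators are bit-reproducible.

They do **not** emulate: bleaching or hemodynamic contamination,
isosbestic channels, emergent (non-scripted) behavior, biophysically
detailed spike shapes, synaptic kinetics diversity, imaging point-spread
functions, section registration error, or atlas alignment. A green test
therefore establishes that the pipeline recovers what it claims from data
matching its assumptions — not that those assumptions hold for any given
rig.

Scripted bouts (rather than emergent exploration) are a deliberate choice:
they make bout-detector acceptance exact, at the cost of unrealistic
trajectories between bouts.

## 7. Numerical choices and degenerate inputs

* Zero-variance inputs (flat mCherry, identical groups, constant images)
  produce flags/warnings and defined results, never crashes or silent NaN.
* The threshold logged by `threshold_channel()` makes every mask
  reproducible; constant channels give empty masks with a warning.
* Tie and boundary conventions: access-resistance QC passes at exactly
  20%; epoch-boundary events go to the light window; two touching somata
  count as two; labels are dense and deterministic in first-voxel order.
* Statistical tests are two-tailed at α = 0.05 throughout, with explicit
  'n.s' flags above 0.05 and no multiple-testing correction (matching the
  reimplemented convention); the report counts the number of tests run so
  a reader can apply their own correction.
* p-values, r, D are range-checked by property tests; type-I calibration
  of the t and KS tests is verified by 2000-replicate null simulations.

## 8. Known limitations

* Absolute sIPSC counts and absolute tracing areas depend on detector and
  threshold settings that the original acquisition tools do not publish;
  only within-pipeline contrasts are meaningful.
* The 10 Hz photometry grid makes sub-0.2 s events undetectable by
  construction, and events with peaks near 3 SD are recovered
  stochastically (see the detection-limit note above).
* The LIF generator's F–I curves are deterministic given R and τ; real
  granule cells adapt, so simulated spike counts are an upper envelope.
* `run_pipeline()` figures (PDF) are optional and not byte-stable across
  runs; the CSV tables are the deterministic contract.
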