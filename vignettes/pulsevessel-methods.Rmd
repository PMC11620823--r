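---
title: "Cardiac-locked vessel segmentation in fMRI space: methods and design notes"
author: "pulsevessel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiac-locked vessel segmentation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Large cerebral vessels occupy a small fraction of fMRI voxels but dominate
their temporal signal: each heartbeat drives an inflow/volume transient that
repeats, beat after beat, with a stereotyped shape. The package models a
vessel voxel's (high-passed) time series as

  y(t) = a · w(φ(t)) + ε(t),

where φ(t) ∈ [0, 1) is the cardiac phase of the acquisition time (the
linear fraction of the RR interval it falls in, taken from the systolic
peaks of a simultaneous finger-plethysmography trace), w is an unknown
periodic waveform, a its amplitude, and ε noise. Non-vessel voxels have
a ≈ 0. Nothing about w is assumed beyond periodicity in φ — the method is
data-driven precisely because w differs across participants and sites.

Three consequences shape the pipeline:

* **Phase binning.** Averaging samples within N equal phase bins estimates
  w at the bin centers regardless of heart-rate variability, because phase,
  not time since the peak, is the alignment variable.
* **Split-half reproducibility.** If the waveform is real, two disjoint
  random halves of the timepoints yield two independent estimates of w that
  correlate strongly; for noise the correlation scatters around zero. The
  mean over 100 random splits is a per-voxel pulsatility score in [−1, 1].
* **Template refinement.** The mean waveform of a high-confidence arterial
  region is a better-conditioned target than a half-series waveform, so the
  final segmentation correlates every voxel's full-series waveform against
  this template and thresholds against the brain background.

Temporal aliasing is irrelevant to the alignment: phase binning is not a
spectral operation, so cardiac frequencies above the temporal Nyquist rate
(1/(2·TR)) still bin correctly. Only the spectral *verification* module has
to fold the cardiac line to its alias frequency, which it does and flags.

## Pipeline and parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `nTrim` | 10 | volumes | discard non-steady-state volumes |
| `cutoff` | 0.005 | Hz | high-pass cutoff; removes DC and drift |
| `filterOrder` | 2 | — | Butterworth order (applied forward–backward) |
| `nBins` | 20 | — | phase bins per cardiac waveform |
| `nRepeats` | 100 | — | random splits in Step 1 |
| `ppgThreshold` | 0.30 | — | minimum PPG quality score |
| preliminary rule | mean + 3 SD | — | threshold over all brain voxels |
| refinement quantiles | 0.99 / 0.95 | — | artery / SSS background cutoffs |
| `volTol` | 0.01 | — | relative volume change declaring convergence |
| `maxIter` | 20 | — | refinement cap |

**nBins = 20** balances phase resolution against bin occupancy: with
~220–440 timepoints per (half-)series, 20 bins leave ≥ 10 samples per bin,
keeping bin-mean noise well below a pulsatile amplitude of twice the noise
SD. The bin count is exposed because long acquisitions can afford more.

**Zero-phase filtering.** The high-pass is applied forward and backward
(`signal::filtfilt`), so the filter's phase response cannot rotate the
cardiac waveform relative to the PPG. Each voxel is demeaned before
filtering and any residual mean is removed afterwards; this makes DC
removal exact rather than asymptotic (finite-length forward–backward
filtering leaves edge transients whose mean is small but nonzero), and the
whole operation remains linear. Series shorter than 8 timepoints are
rejected outright — a 0.005 Hz filter is meaningless there.

**PPG quality.** The score is the fraction of 0.5–3 Hz spectral power
lying within ±0.15 Hz of the spectral peak in the 0.6–2.0 Hz heart-rate
band and of its first harmonic. A clean pulse concentrates essentially all
of its band power there (score near 1); broadband noise yields about
2·(0.3)/2.5 ≈ 0.24. The pass threshold of 0.30 sits between those regimes
and is configurable; both the score definition and the threshold are this
package's concrete choices.

**Motion gate.** "Maximum translation greater than one voxel dimension" is
read literally as the maximum absolute per-axis translation relative to the
realignment reference, compared against the smallest voxel edge. A
Euclidean-norm variant and frame-to-frame differencing are available behind
arguments, since either reading is defensible.

**Peak detection.** The PPG is band-passed to 0.5–3 Hz; local maxima with
minimum separation 0.3 s are kept if they reach half the median pulse
amplitude. Sub-0.3 s intervals are resolved by dropping the smaller peak;
gaps longer than 2 s are bridged with evenly spaced surrogate beats so that
downstream RR intervals remain physiological. The detected peak sits at the
band-passed pulse maximum, so the phase origin is a detector convention: a
constant rotation shared by every voxel, with no effect on any correlation
in the pipeline.

**Phase conventions.** Acquisition time of a slice is volume onset plus its
slice offset when slice timing is known, and onset + TR/2 otherwise.
Timepoints before the first or after the last detected peak are invalid and
excluded everywhere. Empty phase bins are filled by circular linear
interpolation and flagged; a waveform with more than 25% interpolated bins
is rejected (from template use, and for that voxel/repeat in the maps).

## Numerical choices

* Correlation follows the (N−1)-normalized standardized cross product over
  the N phase bins — the ordinary Pearson coefficient, computed exactly in
  that form. Zero-variance waveforms give NaN, and NaN voxels never enter
  thresholds, quantiles or masks.
* Thresholding is strictly `>` ("exceeding" the cutoff), both for
  T_preliminary and the refinement quantiles.
* Quantiles use linear interpolation between order statistics
  (`stats::quantile` type 7), stated for bit-reproducibility.
* The randomized split step is governed by one integer seed, recorded in
  the result; identical inputs and seed reproduce masks and iteration
  traces bit for bit.
* Convergence compares consecutive volumes: |V_k − V_{k−1}|/V_{k−1} < 0.01.
  Hitting `maxIter` (including by oscillation) returns the last mask with
  `converged = FALSE` rather than an error; an empty mask at any iteration
  is an error, as is an empty preliminary region.
* Volumes are reported in cm³ = voxel count × voxel volume / 1000.
* The SSS branch: candidate voxels are the general SSS ROI restricted to
  the brain; the background population for *both* targets is brain voxels
  outside both general ROIs. The alternative literal reading ("exclude all
  brain voxels") would leave no background to compute the quantile in, so
  it cannot be meant. Both targets start refinement from the same
  preliminary-artery waveform.
* ICC(A,1) is computed from the two-way ANOVA mean squares,
  (MSR − MSE)/(MSR + (k−1)MSE + (k/n)(MSC − MSE)), with the F-based 95%
  confidence interval (Satterthwaite degrees of freedom) and the F-test of
  MSR/MSE against ICC = 0. Percent overlap defaults to the
  intersection-over-reference reading |X∩Y|/|Y|·100; the size-ratio variant
  |X|/|Y|·100 is available via `method = "size-ratio"` because the two
  readings of the overlap formula disagree and both are reported in
  practice by swapping the reference.

## The synthetic phantom

`generatePhantom()` builds the validation dataset the tests and the
acceptance script run on. Defaults: a 32³ grid of 2.5 mm voxels, 450
volumes at TR 0.5 s, heart rate 66 bpm with 2 bpm beat-to-beat jitter,
pulsatility amplitude twice the noise SD, background drift at half the
noise SD (0.01–0.05 Hz), schematic vessel geometry (an arterial ring near
the grid center, an SSS tube running anterior–posterior near the top of the
brain), and general ROIs built by dilating the truth tubes with a 5³ cubic
kernel. Voxel size and the pulsatility/noise ratio reflect a 3 T
multiband acquisition with simultaneous PPG; jitter keeps RR intervals
incommensurate with TR so phases cover [0, 1) (an exactly constant RR that
divides TR rationally would leave most phase bins empty — a degenerate
sampling design, not a failure mode of real data). At 66 bpm and TR 0.5 s
the cardiac line actually sits just above Nyquist; segmentation is
unaffected and the spectral module reports the folded frequency, which the
tests exercise.

The phantom emulates: cardiac-locked, slice-time-aware pulsatility with a
non-sinusoidal asymmetric waveform (sharp systolic peak at phase ≈ 0.15,
dicrotic bump at ≈ 0.5); a PPG built from fast-rise/slow-decay pulses whose
maxima coincide with the beats; drifting heart rate; overly inclusive ROIs;
optionally a half-amplitude partial-volume shell around each tube; and a
venous phase lag of 0.05 cycles for the SSS.

It does **not** emulate: respiration, motion and spin-history artifacts,
EPI distortion, vascular territory anatomy, T2* baseline structure, or
spatially correlated noise. Passing the phantom recovery tests therefore
shows the algorithm is implemented correctly and behaves as designed under
its own signal model — it does not certify performance on real data, where
registration of the general ROIs, PPG quality and distortion dominate.

## Problem sizes used by the tests

The unit-test phantom is a 16×16×12 grid with 350 volumes and single-tube
vessels; the acceptance checks run the full default 32³/450-volume phantom
(about half a minute end to end), a 1000-voxel pure-noise cube at 100
splits for null calibration, 10⁵ uniform values for the quantile check, and
a 400 × 4 volume table for the ICC recovery simulation. These sizes were
chosen so the whole suite exercises every code path at full parameter
settings (100 repeats, 20 bins) while staying comfortable on a laptop.

## Known limitations

* The pipeline assumes the PPG and fMRI clocks are already synchronized;
  `t0` is exposed (trace start relative to the first retained volume, or to
  the scan start via `physioStart = "scan"`) because acquisition setups
  differ and no convention can be inferred from the data.
* General ROIs must already live on the fMRI grid; no registration or
  resampling is performed, and geometrically inconsistent inputs are
  rejected rather than resampled.
* The split-half mean correlation of a *fixed* noise realization has a
  voxel-conditional component that more repeats cannot average away;
  repeats reduce split-sampling noise (≈ 1/nRepeats in variance) but the
  map's voxel-to-voxel scatter under the null plateaus. The data-driven
  thresholds (mean + 3 SD, background quantiles) are exactly what makes the
  method robust to this.
* With very short series or strongly quantized phases, more than 25% of
  bins can come up empty; such waveforms are rejected rather than
  silently interpolated into the statistics.
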