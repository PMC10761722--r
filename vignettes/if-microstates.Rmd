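---
title: "Leading-phase microstates from instantaneous frequency: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leading-phase microstates from instantaneous frequency: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ifstate)
```

# The model

`ifstate` treats resting-state EEG as a set of narrowband oscillators (one
per electrode) whose *instantaneous frequencies* transiently desynchronise:
at any moment one scalp region may run slightly fast relative to the scalp
average, i.e. its phase *leads*. The package's claim is operational, not
biophysical: if such leading episodes exist and are regionally organised,
the pipeline below detects them, segments the recording into leading-phase
microstates, and quantifies their statistics.

The processing chain per recording is:

1. **Band-pass 4–13 Hz** (theta + alpha), zero-phase.
2. **Trim 5 s** from each end (filter transients).
3. **Hilbert transform** per channel; wrapped phase θ(t) ∈ [−π, π] and
   analytic amplitude.
4. **IF** = (rate / 2π) × central difference of the unwrapped phase,
   then a 0.1-s running median to remove phase slips.
5. **Deviation field** dIF(t) = IF(t) − cross-channel mean: positive =
   leading, negative = delaying. The per-sample channel mean of dIF is 0
   by construction.
6. **GF-IF** = cross-channel SD of dIF, smoothed with a 0.025-s running
   median. High GF-IF = strong regional specialisation.
7. **Segmentation**: dIF topographies at GF-IF local maxima, pooled over
   *all* subjects of both groups, are clustered with Euclidean k-means
   (k = 4). Transitions are placed at GF-IF local minima; each
   inter-minima segment is assigned the cluster nearest to the dIF vector
   at its contained maximum.
8. **Metrics**: emergence frequency (segments/s, overall and per state),
   occurrence-duration rate (time share per state; sums to 1), and the
   k × k transition matrix over consecutive peaks (self-transitions
   counted).

Assumptions worth stating: inputs are artifact-free epochs (no rejection or
ICA is performed); the band-limited signal is well enough behaved that the
analytic phase is meaningful (narrowband assumption); and volume conduction
is not corrected, so "region" means a set of electrodes, not sources.

# Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| band | 4–13 | Hz | dominant resting rhythms in both groups; a 2–20 Hz option mirrors conventional microstate bands |
| filter order | 4 (×2 passes) | – | Butterworth, forward–backward; standard EEG practice |
| trim | 5 | s | removes filter transients; at 200 Hz this is 1000 samples per end |
| IF median window | 0.1 | s | suppresses phase-slip spikes; 21 samples at 200 Hz (forced odd) |
| GF-IF median window | 0.025 | s | removes high-frequency ripple; 5 samples at 200 Hz |
| k | 4 | – | the standard cluster count in microstate work; configurable |
| k-means restarts | 50 | – | k-means++ seeding, best inertia kept |
| PSD window | 5 | s | Hann, 50% overlap, grid 0.001–1 Hz in 0.001-Hz bins |
| SampEn | m = 2, r = 0.2 | – | the standard embedding/tolerance for physiological series |
| MSE scales | 1–20 | – | scale τ corresponds to τ/rate seconds (the GF-IF keeps the 200-Hz grid) |
| IAAFT | 10 surrogates, 100 iterations | – | iteration-capped, ending on the rank step |
| FDR level | q = 0.05 | – | BH step-up over fixed family sizes (1000 / 20 / k+1 / k / k²) |

# Numerical choices

**Zero-phase filtering.** IF is a phase derivative; any filter phase
distortion would bias it directly. The band-pass is therefore applied
forward–backward (`signal::filtfilt`), giving an effective 8th-order
magnitude response and exactly zero phase.

**Central difference.** IF uses the central difference of the unwrapped
phase rather than a forward difference, which removes the half-sample
timing bias; the one differentiation sample at each end is dropped, so the
IF field is two samples shorter than the trimmed recording.

**Median filters at edges.** Running medians use a symmetric window
truncated at the series boundaries (shrinking window) rather than padding:
no data are fabricated at epoch ends. Windows are forced odd.

**Population SD.** The GF-IF uses the divisor-n SD across channels
(configurable to n−1). With 16 channels the difference is a constant
factor 1.033 and does not move extrema locations.

**No IF clipping.** IF values are not clipped to the filter band; the
median filter alone handles slips. The band-limited input makes sustained
out-of-band excursions self-limiting.

**Extrema and alternation.** Local extrema are strict neighbour
comparisons on the run-length-compressed series, so plateaus collapse to
their midpoint sample. Alternation (exactly one maximum between
consecutive minima) is enforced by keeping the most extreme member of any
same-type run; the evaluated span is clipped to [first minimum, last
minimum], which makes occurrence rates sum to exactly 1 and every segment
contain exactly one peak.

**k-means.** k-means++ seeding with 50 restarts and Lloyd iterations
(`stats::kmeans`), best within-cluster sum of squares kept; a restart that
produces an empty cluster is discarded and the next one used. The fit is
deterministic given the seed. Topographies are clustered *as-is* — no
polarity invariance, because the dIF sign (leading vs delaying) is
physically meaningful, unlike amplitude-microstate maps. If the input has
fewer distinct rows than k the model degenerates gracefully to the
distinct topographies (all assignments tie-break to the lowest index).

**Ties.** Nearest-centroid assignment breaks ties toward the lower state
index. State labelling gives each centroid the region set (frontal /
occipital / left / right, from the montage's region map) with the highest
mean centroid dIF; when two centroids claim the same region the one with
the larger margin (best minus second-best region mean) wins and the other
takes its best still-free region with positive dominance, else keeps a
generic `state_j` name.

**SampEn conventions.** Sample entropy uses the Chebyshev norm, strict
`< r` matching, self-match exclusion, and N−m templates for both m and
m+1 (Richman–Moorman pair counts), computed in a small C++ kernel. The
series is z-scored once at scale 1 and r = 0.2 is held fixed across all
coarse-graining scales, so the MSE profile reflects the dynamics rather
than a rescaled tolerance. Scales with no template matches return a
flagged `NA`, never a silent zero. A constant series has entropy 0.

**Welch PSD.** Hann windows, 50% overlap, no detrending; segment FFTs are
zero-padded to rate/0.001 points so the evaluated grid is exactly
0.001–1.000 Hz in 0.001-Hz steps (1000 bins), reported one-sided in
dB/Hz. Note the resolution limit: a 5-s window resolves ~0.2 Hz, so
spectral lines below that cannot localise at their own bin — the
line-location test uses a 0.5 Hz tone for this reason.

**IAAFT.** The surrogate loop alternates spectrum imposition (original
Fourier amplitudes, current phases) and rank remapping onto the sorted
original, runs a fixed 100 iterations, and ends on the rank step, so the
surrogate's value multiset equals the original's exactly while its power
spectrum converges to relative RMSE well below 1e-2 on smooth series.
Iteration-capped (not tolerance-based) termination keeps runs
deterministic and comparable.

**FFT lengths.** GF-IF series lengths routinely contain large prime
factors (e.g. 9998 = 2 × 4999 after the 5-s trim and differentiation
edge), for which R's mixed-radix FFT degrades to near-quadratic cost. The
package transparently switches to Bluestein's chirp-z algorithm for such
lengths (three power-of-two FFTs, cached chirp factors), keeping IAAFT
fast without altering results (agreement with the direct FFT is at the
1e-11 level).

**Degenerate inputs.** Constant channels are rejected before the Hilbert
step; a flat GF-IF (or any series with fewer than two minima) raises a
typed "too-short-dynamics" condition; zero-variance groups or difference
vectors raise degenerate-test errors instead of emitting infinite
statistics.

# Statistics

Group comparisons use Student's pooled-variance two-sample t (the
conventional default where nothing more specific is stated; Welch's
variant is a one-line change) with the sign convention AD − HC: positive t
means larger in the AD group. The surrogate analysis uses a paired t of
original-vs-surrogate-mean SampEn across subjects at each scale. All
families are FDR-controlled by Benjamini–Hochberg step-up at q < 0.05 over
*declared, fixed* family sizes — 1000 PSD bins, 20 MSE scales, k+1
emergence tests, k occurrence tests, k² transitions — and a family-size
mismatch aborts rather than silently adjusting. MMSE correlations are
Pearson r over AD subjects, FDR-corrected within each metric family. Raw p
values are always carried alongside the flags.

Design choices on genuinely open points: the IF is median-filtered *after*
differencing (not the phase before), matching the reading that the filter
targets the IF; pooled clustering concatenates peaks over all subjects of
both groups rather than averaging per subject (the literal "pooled"
reading; per-group fitting is available for sensitivity analysis);
"sustaining duration" is exposed as the per-segment duration vector
without a dedicated summary statistic.

# The synthetic generator

`generate_recording()` drives every end-to-end test. A hidden semi-Markov
process draws a leading region i.i.d. from `state_priors` with
Gamma-distributed dwell times (mean 0.4 s, shape 2); each channel is
A·cos(φ(t)) with instantaneous frequency `base_freq` (+ `delta_f` = 1 Hz
while the channel belongs to the active region), phase accumulating
*continuously* across switches so no broadband transients leak into the
band. Pink (1/f) noise at 0.3 of the oscillation amplitude is added; white
noise is available for analytic checks. HC-like subjects use
`base_freq` = 8.6 Hz and uniform priors; the AD-like variant lowers the
base rhythm to 7.8 Hz (the slowing effect) and the occipital prior from
0.25 to 0.10. Cohort defaults are 18 HC + 16 AD, 60-s epochs at 200 Hz,
16 channels in the standard 10–20 montage order; AD-like subjects receive
integer MMSE scores drawn uniformly from 10–26.

What the generator *emulates*: narrowband rhythms, regional IF leading
with seconds-scale dwell, group effects in rhythm frequency and occipital
occupancy, 1/f background. What it does *not* emulate: volume conduction
and electrode cross-talk, non-stationary amplitude dynamics, artifacts,
inter-subject variability of the base rhythm (each group's base frequency
is fixed, so between-subject variance of the mean IF comes only from noise
and state realisation — group-mean-IF t statistics on synthetic cohorts
are therefore far larger than anything a real cohort would produce), or
genuine neural coupling. Passing the recovery tests therefore shows the
*pipeline* is correct and sensitive under its own model class, not that
real EEG contains these states.

# Problem sizes in the test-suite and acceptance script

The package chooses deliberately modest problem sizes: planted-state
recovery uses 20 recordings × 60 s; group-effect recovery uses 20
replicate cohorts of 18 + 16 subjects × 60 s; oracle equivalence uses 50
random series of length ≤ 300; surrogate checks use N = 10000 fixtures.
The acceptance script analyses one full default cohort (34 × 60 s) with
the complete dynamics suite (10 surrogates × 20 scales per subject).

# Known limitations

- EDF support covers continuous EDF with uniform per-signal rates;
  EDF+ annotation channels are ignored, discontinuous files are not
  handled.
- The minima-bounded segmentation has no temporal smoothing beyond the
  GF-IF median filter; very noisy recordings over-segment (emergence
  frequencies then exceed the underlying switching rate, as the generator
  itself demonstrates).
- No silhouette-style selection of k; k is a user choice (default 4).
- No re-referencing: IF inherits whatever reference the input has.
- The finite-window Hilbert transform leaks at epoch boundaries; the 5-s
  trim removes the worst of it, but shift-equivariance of the IF field is
  approximate (at the 0.02 Hz level deep in the interior), not exact.
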