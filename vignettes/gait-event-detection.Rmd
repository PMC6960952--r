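---
title: "Determining gait events from foot-mounted accelerometers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining gait events from foot-mounted accelerometers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitevents)
```

## The problem

A gait cycle of one foot contains four basic events: heel strike (HS), toe
strike (TS), heel off (HO) and toe off (TO). Optical motion capture dates
them precisely but needs a laboratory; a tri-axial accelerometer taped to the
heel and another to the toe can be worn anywhere. `gaitevents` determines the
four events from those two acceleration records alone, and validates the
result against a reference (motion capture, or the exact ground truth of the
built-in simulator) with per-event error statistics and Bland-Altman limits
of agreement.

The pipeline has five stages, run per sensor site:

1. **Denoising** by the wavelet modulus-maxima criterion.
2. **Gravity removal**: subtract the whole-record mean from the vertical
   axis.
3. **Phase segmentation**: threshold the smoothed jerk magnitude to find the
   *flat* phases in which the foot rests on the ground.
4. **Displacement reconstruction**: double integration in the frequency
   domain, followed by wavelet removal of the integration trend.
5. **Event determination**: within each flat phase (plus a margin), the
   strike event is the first displacement trough reached by a sharp drop and
   the off event is the first following trough left by a sharp rise.

## The model, stage by stage

### Modulus-maxima denoising

Let $W_a(2^j, i)$ be an undecimated wavelet transform of the record at
dyadic scale $2^j$. For a feature of Lipschitz regularity $\beta$ the local
maxima of $|W_a|$ obey $\log_2 |W_a(2^j, i)| \le \log_2 k + j\beta$: smooth
signal structure ($\beta > 0$) grows across scale, noise ($\beta < 0$)
decays. The implementation uses the additive B3-spline (starlet) transform,
whose detail bands are differences of successive smoothings, so synthesis is
exact by summation. Maxima at adjacent scales are linked into chains when
their positions differ by at most $\lceil 2^j/2 \rceil$ samples (the cone of
influence widens with scale); $\hat\beta$ is the least-squares slope of
$\log_2$ magnitude against scale index; chains with $\hat\beta \ge 0$ are
kept. Single-scale chains cannot demonstrate growth and are conservatively
classified as noise. Reconstruction restores the original coefficients in
the kept chains' neighbourhoods, zeroes the rest of the detail bands, keeps
the deep approximation, and refines by alternating projections between that
constraint set and the range of the transform (at most 30 iterations,
relative $L_2$ tolerance $10^{-6}$).

A note on the taxonomy: an isolated Dirac impulse has $\alpha = -1$ and its
maxima decay *faster* than those of white noise, so an impulse is removed,
not kept; the criterion protects smooth structure and acceleration
transients whose displacement is continuous (slope breaks, $\alpha = 1$),
which is exactly what foot impacts look like when the trajectory is twice
differentiable.

### Gravity removal

$a_{Sz}(i) \leftarrow a_{Sz}(i) - \frac1N \sum_{i=1}^N a_{Sz}(i)$, over the
whole continuous record (not per segment), after denoising.

### Jerk-threshold segmentation

The comprehensive change rate of acceleration is the discrete jerk
magnitude $J_{aS}(i) = \sqrt{\Delta a_x^2 + \Delta a_y^2 + \Delta a_z^2}$,
smoothed by a trailing (causal) moving average of 30 ms — the leading
samples use the truncated available window. A sample is non-flat when the
smoothed jerk exceeds $th_S = r \cdot \max_i ja_S(i)$ with $r = 0.05$ by
default; the threshold scales with each record, so no absolute calibration
is needed, and the subsequent trough search makes the final event times
insensitive to the exact choice of $r$. Runs shorter than 100 ms are
absorbed into their neighbours: no support phase of steady walking is that
short, while the model's swing jerk passes through zero briefly mid-swing
and would otherwise leave decoy "flat" fragments.

### Frequency-domain double integration

With $A_{sz}(k)$ the DFT of the vertical acceleration, displacement is
$d_{sz}(n) = \mathrm{IDFT}[A_{sz}(k)/(j\omega_k)^2]$ with
$\omega_k = 2\pi k f_s / N$ for $k \le N/2$ and conjugate-symmetric negative
bins, so the inverse transform is real. The DC bin, where the operator is
singular, and every bin below 0.1 Hz are zeroed; the $1/\omega^2$
amplification of near-DC noise is otherwise unbounded.

Double integration of a signal whose mean and slow drift are not exactly
zero leaves a large trend. It is removed by an 8-level wavelet decomposition
(sym8 by default, db6 selectable) with the deepest approximation band set to
zero; optionally the detail bands are also soft-thresholded at the universal
threshold $\sigma\sqrt{2\ln N}$ with $\sigma$ from the finest band's median
absolute deviation, but the default leaves them untouched.

At 1000 Hz, 8 levels place the zeroed band at 0–1.95 Hz. This removes the
trend *and* the fundamental of a ~1 s gait cycle: the detrended displacement
is a band-passed version of the true one, superposing a slow ripple
(~±30 mm, slopes up to ~0.5 m/s) on the stance plateau. Every trough
therefore shifts by (ripple slope)/(trough curvature); with realistic
landing curvature of tens of m/s² this is a systematic error of roughly
5–15 ms — visible in the simulator as a noiseless floor — and content at or
below ~2 Hz cannot survive this operation at all.

### Trough-based event determination

Within each interior flat interval, extended by a 120 ms margin on both
sides, all strict local minima of the detrended displacement are annotated
with mean slopes over the preceding and following 50 ms. The strike (HS for
heel, TS for toe) is the first trough with preceding slope
$\le -0.05$ m/s; the off (HO, TO) is the first later trough with following
slope $\ge +0.05$ m/s *and* preceding slope below $+0.05$ m/s — a candidate
reached by a steep rise is a noise notch on the post-strike flank, not the
end of the stance plateau. Ties between equal minima resolve to the earliest
index. Cycles are assembled anchored at each HS and must satisfy
HS $\le$ TS $\le$ HO $\le$ TO; intervals or cycles violating this are
skipped with a warning rather than reported.

The margin exists because the displacement minimum at strike precedes the
jerk-quiet region: the foot-flat state begins only after the landing
deceleration and pad-recovery transients plus the smoothing window, about
60–100 ms after heel strike. The margin must also not be much larger, or the
search reaches into the swing descent, where the detrending ripple creates
decoy troughs that a first-match rule would take.

## Tunable parameters

| key | default | unit | role |
|---|---|---|---|
| `denoise$levels` | 4 | scales | dyadic depth of the maxima analysis |
| `denoise$beta_threshold` | 0 | – | minimum growth exponent of a signal chain |
| `denoise$max_iter`, `denoise$tol` | 30, 1e-6 | – | alternating-projection budget |
| `segmentation$r` | 0.05 | – | jerk threshold as a fraction of the record maximum |
| `segmentation$window_ms` | 30 | ms | jerk smoothing window |
| `segmentation$min_segment_ms` | 100 | ms | shortest plausible phase |
| `integration$highpass_hz` | 0.1 | Hz | near-DC cutoff of the integrator |
| `integration$detrend_levels` | 8 | levels | decomposition depth for trend removal |
| `integration$detrend_basis` | sym8 | – | wavelet basis (db6 selectable) |
| `integration$soft_threshold_mode` | ca_only | – | `ca_and_details` also shrinks detail bands |
| `events$slope_window_ms` | 50 | ms | slope estimation window at troughs |
| `events$drop_slope_thresh` | 0.05 | m/s | quantifies "drops sharply" |
| `events$rise_slope_thresh` | 0.05 | m/s | quantifies "rises sharply" |
| `events$search_margin_ms` | 120 | ms | flat-interval extension for the trough search |

All of them live in one configuration object (`gait_config()`, YAML-backed
for the command line), and unknown keys are rejected rather than ignored.

## The synthetic generator

`make_trial()` emulates the acquisition the method is meant for: treadmill
walking at constant speed, a 1000 Hz tri-axial accelerometer per site and a
100 Hz reference trace, 1 s gait cycles with heel contact on phases
[0, 0.45) and toe contact on [0.12, 0.62) (stance fraction 0.6 from HS to
TO), swing peaks of 15 cm (heel) and 5 cm (toe).

The vertical trajectory is a piecewise quintic-Hermite curve, $C^2$
everywhere: flat ground contact; a raised-cosine-like swing arc with its
peak 35 % into the swing (the foot rises quickly after lift and descends
slowly); a landing segment that decelerates from ~1 m/s approach velocity to
a strict minimum *exactly at the strike phase* with ~4 g curvature over
35 ms; and sub-millimetre pad-compression/unweighting transients (0.8 mm
deep, 20 ms) at contact and lift. Those transients are what give the
displacement a strict local minimum at each event time — a perfectly flat
stance has no minimum *at* the contact instant, and nothing for any trough
detector to date. $C^2$ continuity matters for the denoiser: with continuous
acceleration, impacts are slope breaks ($\hat\beta \approx +1$, kept); a
merely $C^1$ model makes them acceleration jumps ($\hat\beta \approx 0$),
which sit exactly on the keep/remove boundary.

Vertical acceleration is the discrete second derivative of this trajectory
plus gravity (9.81 m/s²), white noise (0.2 m/s² SD by default) and a 0.05 Hz
sinusoidal drift (0.1 m/s²) that survives mean subtraction and exercises the
detrending stage. The horizontal axes carry two-tone oscillations gated by a
swing envelope (10 % of the vertical dynamic range) so the 3-D jerk is
realistic during swing and near zero during stance. Trials are bitwise
reproducible from their seed.

What the generator does **not** emulate: soft-tissue resonance and
oscillatory impact transients, sensor-axis misalignment and rotation
(gravity leakage into horizontal axes during swing), treadmill-speed
variability, asymmetric or pathological gait, and motion-capture marker
noise in the reference. Passing the synthetic suite therefore shows the
pipeline recovers events whose displacement signature matches the assumed
trough geometry; it does not certify performance on arbitrary real
recordings.

## Numerical choices

* **Boundary handling of the detrending transform.** The record is extended
  by point-symmetric (odd) reflection — which continues a ramp exactly — and
  a periodized orthogonal DWT is applied to the extended signal, giving
  machine-precision reconstruction; results are cropped back. Even
  reflection folds the meter-scale integration trend at the record ends and
  its leakage survives approximation-zeroing as spurious troughs. Because of
  the crop/re-extend step the detrend operator is a projection only to about
  1 % on pathological (random-walk) inputs, far below its first-pass effect.
* **Integrator conventions.** $\omega_k = 2\pi k f_s/N$; DC bin zeroed
  before the $1/(j\omega)^2$ division; default 0.1 Hz guard band.
* **Maxima bookkeeping.** Strict local maxima only (plateaus yield none);
  chain linking is greedy nearest-position with each maximum used once;
  $\hat\beta$ by closed-form least squares (no model-fit machinery);
  reconstruction caps at 30 alternating projections.
* **Degenerate inputs.** All-zero jerk (threshold undefined), empty
  sequences, too-short signals for a requested depth, and unknown event
  labels all raise typed errors naming the offending quantity; detection
  failures inside one flat interval skip that interval with a warning
  instead of aborting the record.
* **Tie-breaks.** Equal displacement minima resolve to the earliest index;
  event matching is greedy by smallest absolute time difference within
  label, each event used at most once, 100 ms maximum gap.

## Problem sizes used by the test suite

The packaged checks run the full pipeline on 10-cycle trials (10 s at
1000 Hz per sensor) for the headline timing-error measurement, 20 randomized
4-cycle trials for the ordering invariant, and seconds-scale fixtures for
the per-stage oracles. On one CPU the whole suite completes in well under a
minute of compute per heavy block.

## Known limitations

* The 8-level approximation-zeroing at 1000 Hz removes 0–1.95 Hz, including
  the gait fundamental; event timing survives (it is carried by transients)
  but displacement *amplitudes* after detrending are not interpretable, and
  a systematic 5–15 ms trough shift is unavoidable (timing biases of about
  +20 ms reported when accelerometry is compared with motion capture are
  consistent with this mechanism).
* The adaptive jerk threshold assumes the record contains both motion and
  rest; a record that is all-swing or all-stance segments poorly.
* Noise beyond roughly 2.5× the study level (0.5 m/s² SD and up) begins to
  fragment the toe segmentation, whose swing acceleration is only a few
  m/s²; the heel channel is more robust.
* Bland-Altman limits assume approximately normal differences; with fewer
  than ~10 matched pairs per label the limits are unstable.
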