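---
title: "Methods: synthetic two-wavelength PPG and the SpO2 estimation chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic two-wavelength PPG and the SpO2 estimation chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(oximetry)
```

This vignette is the package's account of its science: the measurement
model, the estimation chain, the choices that were genuinely open, and
what the synthetic cohort does and does not establish about real data.

## 1. Measurement model

Transmission pulse oximetry rests on the fact that oxygenated and
deoxygenated haemoglobin absorb red (660 nm) and infrared (940 nm)
light differently. The cardiac pulse modulates the optical path, so each
channel decomposes into a slowly varying DC level and a pulsatile AC
component, and the *ratio of signals*

$$\mathrm{ROS} = \frac{AC_{red}/DC_{red}}{AC_{ir}/DC_{ir}}$$

is a monotone predictor of arterial saturation. Over the clinically
relevant range an affine map suffices:

$$S_pO_2 = a\,\mathrm{ROS} + b, \qquad a < 0.$$

The generator inverts exactly this model. The infrared channel is
$DC_{ir}\,(1 + p\,w(t))$ with $w(t)$ a zero-mean, unit peak-to-trough
cardiac waveform and $p$ the perfusion (AC/DC) fraction; the red channel
scales its relative pulsatile amplitude by
$\mathrm{ROS}(t) = (S_pO_2^{true}(t) - b)/a$. Because both channels share
the same waveform, every downstream distortion that acts multiplicatively
on amplitudes (band-pass attenuation of harmonics, ensemble resampling)
cancels in the ratio, and on clean signal the window-level ROS equals the
encoded value to numerical precision. This *constructive correctness* is
asserted in the tests at 1e-3 and observed near machine precision.

The waveform itself is two Gaussians per period (a fast systolic peak at
0.22 of the cycle, $\sigma = 0.07$; a diastolic hump at 0.52,
$\sigma = 0.13$, amplitude 0.4), normalised to zero mean and unit
peak-to-trough. Zero mean keeps the window average of the channel equal
to its DC level; the secondary hump gives beat detection a realistic
morphology to reject. No optical tissue model (Beer–Lambert path
lengths, scattering) is attempted: ROS is encoded phenomenologically.

## 2. The synthetic cohort

Two protocols are emulated. *Volunteer hypoxemia*: stepwise SpO2
plateaus (defaults 97, 88, 82%) while cycling through 45-s bouts of
walking-in-place, sitting, standing and lying. *Patient daily activity*
(the default): lying, sitting, standing, a 6-min walk and cycling in
fixed proportions (15/15/15/30/25% of the total duration), with
activity-linked plateaus (94, 94, 93, 88, 86%). Plateaus join by 30-s
linear ramps — desaturation and resaturation are physiologically
gradual, and only plateau durations, not transition shapes, are part of
the emulated protocols.

Parameters a practitioner may want to touch, with defaults:

* `sampling_rate_hz = 100` — unstated for the emulated device; kept
  configurable, and validated to exceed 4x the maximum cardiac
  frequency.
* `perfusion_ac_over_dc = 0.02` — typical ear perfusion of a few
  percent; jittered lognormally (sdlog 0.2) across subjects.
* `heart_rate_bpm = 72` with activity offsets (−7 lying … +30 cycling),
  normal between-subject jitter (sd 6 bpm).
* `true_slope_a = -26.8`, `true_intercept_b = 116.9` — the
  patient-population line used as ground truth; negative slope because
  higher ROS means lower saturation.
* `motion_rate_per_min` — Poisson artefact rates per activity
  (0.5/min stationary, 6/min walking, 2/min cycling), so artefacts
  concentrate where motion is.
* `sensor_noise_sd = 0.5` (arbitrary units against DC levels of
  800–1000 and AC amplitudes near 16–20).
* `reference_noise_sd = 0.5`% with AR(1) correlation $\varphi = 0.8$ at
  1 Hz, rounded to integer percent. A commercial reference oximeter
  displays a heavily averaged, integer-rounded value whose jitter at
  stable saturation is about one digit; modelling it with larger,
  uncorrelated noise would make the *reference* — not the sensor under
  test — fail the stability screen, which is not what a validation
  study looks like.
* `abga_noise_sd = 0.5`% for the two arterial blood-gas samples per
  subject (at rest and during cycling).

Motion artefacts are damped oscillations (0.5–2 s, 1–8 Hz, amplitude
5–20x the pulsatile amplitude) built from a waveform shared between the
channels — a common mechanical origin — plus a smaller channel-specific
component, and a lognormal (sdlog 0.25) red/infrared amplitude ratio.
The shared part makes artefacts look *almost* ratio-neutral, the
channel-specific part decorrelates the beat templates so the quality
index can see them. This cross-channel structure is the package's own
choice; only "correlated transients" is contracted.

The mains component (50 Hz) sits at the Nyquist frequency of the 100-Hz
default grid and aliases to an alternating-sign sequence. It is kept as
configured: it is recorded identically in the ambient channel, and is
removed by ambient correction and in any case by the band-pass.

## 3. The processing chain

1. **Ambient correction**: `channel − g·ambient`, with `g` estimated by
   least squares on the sub-0.4-Hz band of both series. Restricting the
   regression to the sub-cardiac band protects the pulsatile band from
   over-subtraction; if the ambient has no sub-cardiac power the gain
   falls back to full-band least squares, and a constant or silent
   ambient channel leaves the signal untouched.
2. **AC extraction**: fourth-order Butterworth band-pass, 0.5–5 Hz
   (cardiac fundamentals of 30–300 bpm), applied forward–backward so
   the response is zero-phase. Signals shorter than three periods of
   the low corner are refused rather than filtered unstably.
3. **Beat detection** on the band-passed infrared channel (the stronger
   SNR): local maxima above 0.4x the rolling 90th percentile of the
   rectified signal (10-s blocks), refractory period 0.33 s enforced
   greedily from the largest peak down — which is what rejects the
   diastolic hump.
4. **Cardiac-gated averaging** per 40-s window (hop 10 s, half-open
   intervals): beat segments are resampled to the median beat length
   and ensemble-averaged. Two robustness elements are part of the
   gating: segments whose length deviates more than 20% from the
   window median are excluded (spurious detections and gaps during
   artefacts are not physiological beats), and the ensemble is a
   20%-trimmed mean per phase point, so a few high-amplitude artefact
   segments cannot leak into the template. On clean windows the
   trimmed mean costs almost nothing (the $\sigma/\sqrt{N}$ noise
   reduction is asserted in tests within a factor 1.5); without these
   two elements, artefact leakage acts as classical regression dilution
   on the calibration slope.
5. **ROS and SQI**: ROS from the template amplitudes and window-mean DC
   levels. The quality index is
   $100 \cdot \max(0, \rho) \cdot \mathrm{reg}$, with $\rho$ the
   correlation between the red and infrared templates and reg the
   fraction of inter-beat intervals within 20% of the window median;
   fewer than two beats scores 0. The deployed sensor's quality index
   is proprietary — only its interface (a 0–100 score with rejection
   strictly below 70) is reproduced, so this explicit surrogate is a
   design decision, chosen to be maximal on clean regular signal and
   monotone non-increasing under broadband noise (both tested).
6. **Rejection**: `too_few_beats` below 20 usable segments, else
   `low_sqi` when SQI < 70 (strictly: a window at exactly 70 is
   retained), else retained. A window's activity label is the modal
   per-sample label, ties broken toward the more movement-intensive
   activity.

## 4. Calibration and evaluation

Retained windows pair their ROS with the window-mean continuous
reference (the pairing rule is a package choice; the study pairs
against a reference oximeter without stating the aggregation).
Calibration is unweighted ordinary least squares with reference SpO2 as
the response — the minimal defensible criterion, and analytically
testable. Cross-fitting is leave-one-subject-out: subject $i$'s line is
fitted on the pooled pairs of all others, and the coefficient summary
reports mean ± sample sd (n−1) across the per-subject models.

Windows whose continuous reference spans more than 2 percentage points
(the usual clinical-significance threshold) or lacks samples are
discarded as `unstable_reference` before analysis. Blood-gas samples
pair with the nearest retained window centre within 30 s — shorter than
any protocol stage — and samples with no such window are dropped.

Statistics follow fixed conventions: bias = mean(est − ref); precision
= sample sd (n−1); $A_{RMS} = \sqrt{\mathrm{mean}((est-ref)^2)}$ with
the n denominator its definition implies. The identity
$A_{RMS}^2 = bias^2 + \frac{n-1}{n}\,sd^2$ is asserted in tests at
1e-10, so the conventions are self-documenting; with the population-sd
convention it reduces to $A_{RMS}^2 = bias^2 + sd^2$, which is the form
that makes a reported (bias, SD, A_RMS) triple internally consistent.
Bland–Altman limits are mean ± 1.96 sd of the differences. Strata are
walking vs stationary (everything else, cycling included), each with
its own rejection denominator; empty strata are absent, not zero.
Pearson correlation is reported with a two-sided p-value and flagged
undefined when either series is constant.

## 5. Problem sizes and reproducibility

The reference experiment everywhere — tests, the worked example, the
acceptance script — is a 15-subject patient cohort at 100 Hz, 1200 s
per subject (about 117 windows each, 1755 total). Unit and property
tests use shorter single-subject recordings (400–600 s). All
randomness flows from configured seeds through deterministic
per-subject and per-stage sub-streams; identical configurations
reproduce identical outputs byte for byte, which the tests assert.

Numerical details worth knowing: signals are demeaned before
forward–backward filtering (the filter's implicit zero-padding would
otherwise turn a 1000-unit DC level into edge transients that corrupt
the first and last windows and the ambient gain estimate); window
boundaries are half-open so no sample is double-counted; clamping of
reported SpO2 to [0, 100] preserves the unclamped value for internal
use; degenerate inputs (zero-variance designs, all-identical ROS,
windowless recordings, empty pair sets) raise explanatory errors rather
than returning silent zeros.

## 6. What the synthetic cohort does and does not show

The generator establishes that the chain is *internally correct*: it
recovers an encoded calibration line through leave-one-out
cross-fitting, its quality index concentrates rejection where artefacts
are, and its agreement statistics satisfy their defining identities. It
does not establish performance on real ear recordings: real PPG has
baseline wander correlated with respiration, perfusion that varies with
temperature and posture, optical coupling changes the artefact model
does not capture, and reference devices with their own motion
sensitivity. Headline numbers from any real study (correlations,
rejection rates) depend on those recordings and are deliberately not
claimed; the synthetic experiment's role is to verify the machinery
that would process them.
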