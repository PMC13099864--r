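---
title: "How batnav models biosonar target search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How batnav models biosonar target search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batnav)
```

## The problem

Big brown bats emit short FM pulses sweeping from about 100 kHz down to
20 kHz and perceive both target range and target shape as *delays*.  Range
comes from the overall pulse-to-echo delay.  Shape comes from the target's
glints: discrete reflecting points whose mini-echoes arrive a few tens to a
few hundreds of microseconds apart.  Reflections closer together than the
inner ear's integration time (~350 microseconds) merge into a single echo
whose spectrum carries interference nulls spaced `1/dt` in frequency;
reflections farther apart resolve as separate echoes.  The spectrogram
correlation and transformation (SCAT) receiver estimates overall delay by
pooling per-frequency timing registrations (correlation) and recovers the
glint delay by inverting the null spacing (transformation, `df = 1/dt`).

`batnav` couples this receiver to a simple flight controller and runs an
agent-based search: a model bat flies through a 2D range/crossrange arena of
two-glint targets, classifies each approached target by its glint delay, and
stops when it captures the one target whose reflections are 100 microseconds
(17 mm end-on at c = 340 m/s) apart.

## The receiver

**Filterbank.** Each of 81 channels (20 to 100 kHz, 1 kHz apart) is a
zero-phase Gaussian bandpass filter applied in the frequency domain, so the
bank is group-delay equalised by construction.  The auditory integration
time is realised through the channel's temporal spread: the time-domain
sigma is `smoothing_time / (2 sqrt(2 log 2))`, which makes the envelope
ridge of a swept or impulsive input 350 microseconds wide at half maximum.
The matching frequency sigma (~1.07 kHz) lies inside the physiological range
of tuning widths.  This one constant does double duty deliberately: a wider
channel cannot resolve interference nulls for glint delays approaching the
integration limit (the null modulation falls off as
`exp(-2 (pi sigma_f dt)^2)`, which is 1e-4 at 300 microseconds for a 4 kHz
channel), while a narrower channel would smear the ridge beyond the
integration time.  Envelopes are evaluated on a decimated grid (16
microsecond steps) via a zoom transform — only the FFT bins inside each
channel's passband are inverted — and threshold crossings are interpolated
linearly between grid points, which retains microsecond timing because the
envelope varies on the integration-time scale.

**Detection events.** Ten threshold levels span 30 dB to 3 dB below the
segment's peak envelope (the count is part of the model; the values are
configuration), clipped from below at five times the segment's median
channel envelope: the echo ridge is sparse in the analysis window, so the
median estimates the noise level, and thresholds under it would fire on
noise alone and flood the event matrix at moderate SNR.  Each channel/level cell records the upward crossing times
of the channel envelope.  Amplitude-latency trading — weaker sounds are
registered later — is modelled as an added latency of 15 microseconds per dB
of the channel's peak below the reference (a configurable slope inside the
physiological range).  This is what carves the scalloped event pattern
around spectral nulls: attenuated channels report late.

**Dechirping and delay pooling.** Echo event times are dechirped by
subtracting the broadcast's own event matrix cell by cell, collapsing the
sweep so a delayed broadcast copy lands on one residual delay everywhere.
Overall delay is a trimmed mean (trim 0.25) over the defined cells, with a
confidence score equal to the fraction of cells within 50 microseconds of
the estimate.  Two residual matrices are kept: the raw one retains the
latency-trading retardation and is what the null cross-check reads; the
pooled delay and the multimodality clustering use latency-corrected
residuals, since the added latency per channel is a known quantity of the
receiver (this is also what makes event times nonincreasing across threshold
levels after correction).  Without the correction, null-channel retardation
(up to ~450 microseconds) splits merged echoes into spurious modes.

**Resolved echoes.** All crossing residuals are clustered by a
single-linkage gap rule with the integration time as the window; clusters
holding at least 10 cells are separate reflections.  A 1000 microsecond
glint pair therefore appears as two delays 1000 microseconds apart and no
merged-spectrum glint estimate, which is exactly how the receiver
distinguishes "shape inside the integration window" from "two things".

**Nulls and transformation.** The spectral profile is the per-channel peak
envelope inside a window that tracks the echo's ridge (broadcast ridge time
plus the reflection's delay, half-width 1.5 integration times).  Null
candidates are local minima with at least 5% prominence and 2 kHz spacing,
refined to sub-channel precision by parabolic interpolation, and
cross-checked against event retardation relative to neighbouring channels
within the echo's own residual cluster.  Channels within 4.4 kHz of the band
edges are not eligible: the broadcast's amplitude taper shades them and
biases minima there.  The glint delay is the reciprocal
of the mean adjacent null spacing, with two guards: gaps larger than 1.6
times the smallest gap are excluded (a missed weak null doubles one gap),
and at least three nulls are required, because a single pair of minima
carries no evidence of periodicity (band-edge taper shoulders can fake one).
A resulting delay at or beyond the integration time is discarded: merged
spectra only exist below it.  The smallest spacing in play, 30 microseconds,
still leaves three nulls inside the band.

## Binaural localisation and control

Azimuth comes from the interaural delay difference,
`asin(c (tL - tR) / a)` with a 14 mm ear separation.  The difference is
measured cell by cell: every channel/threshold cell whose residual falls
near the tracked reflection in both ears contributes its left-minus-right
difference, and the median is taken.  Pairing the same cells across ears
cancels the interference and thresholding distortions common to both, which
independent per-ear pooled delays do not; the paired estimate is good to a
microsecond or so, i.e. a few degrees.

The controller separates head and body: the sonar beam may turn 60 degrees
per epoch and fixates on the selected target within an epoch or two, while
the flight heading turns toward the beam at most 15 degrees per epoch, so
flight visibly lags the beam and the approach paths curve.  The bat advances
0.1 m per epoch (about 1 m/s at a 10 Hz pulse rate; this reproduces the
characteristic ~20-epoch approach to a single target 1.5 m away).
Classification waits until the target sits within 8 degrees of the beam
axis: the glint spacing is then observed nearly end-on, and 8 degrees leaves
room for the one-epoch parallax between aiming and moving while costing
under 1% in aspect projection.  A target is accepted when its merged glint
delay is within 20 microseconds of the desired 100 and it did not resolve
into separate reflections; otherwise it is rejected and remembered for the
rest of the scene, and the search re-engages the next nearest target.
Accept/reject verdicts commit only when two consecutive clean looks agree,
so one distorted spectrum cannot mis-classify a target.  Capture requires
passing within 0.1 m of an accepted target (checked against the motion
segment so a step cannot jump over the capture disk); once the accepted
target is within 0.6 m the bat brakes and may turn at the beam rate — a
terminal capture maneuver, without which the flight turn limit sets a
minimum orbit radius of ~0.38 m and the approach can limit-cycle just
outside the capture disk.

## The epoch loop and its bookkeeping

One epoch is one broadcast: synthesize the binaural echo mixture of every
target in the beam's front hemisphere (delayed, scaled broadcast copies at
exact mouth-to-glint-to-ear path delays; additive white noise at 40 dB SNR
re a single glint), analyze each ear, steer, possibly classify, advance.

A few bookkeeping rules connect estimates to targets, and they are worth
stating because they use the synthesizer's ground truth the way the original
work labels its targets T1...Tn:

- **Attribution.** A resolved reflection is attributed to the target whose
  true delay (either glint) is nearest, within 0.5 ms.  The epochs-per-target
  metric and the rejection memory are keyed to these labels.
- **Identity-checked tracking.** Each epoch the tracked target must
  re-appear as an attributed reflection near its predicted delay; the
  nearest-mode-only alternative silently drifts onto neighbouring (or
  already rejected) targets crossing the gate.
- **Contaminated looks defer classification.** When a foreign reflection
  lies within 1 ms of the tracked one, it leaks into the spectral-profile
  window and distorts the null pattern, so merged-spectrum decisions wait
  for the geometry to separate the delays — with one exception: a resolved
  pair of the target's own glints is rejected on timing alone, which does
  not need a clean spectrum.
- **Abandonment is not rejection.** A target that stops producing usable
  echoes (typically merged with a neighbour or behind the beam) is abandoned
  after a few retries with a 10-epoch cooldown and re-engaged later from
  different geometry; the same applies to engagements that stall beyond 60
  epochs without a classification.  Rejection is reserved for actual
  classification verdicts, so the desired target can never be discarded by
  bad luck of geometry.

Per-run noise is drawn from a stream seeded once per run, so identical
(scene, configuration, seed) triples reproduce bit-identical searches.

## The synthetic scenes

Targets are two-glint reflectors; spacings are specified as end-on two-way
delays and converted via `spacing_m = c dt / 2` (c = 340 m/s makes 100
microseconds exactly 17 mm).  By default targets are *observer-facing*: the
glint axis points along the line of sight at each observation, so the
projected delay always equals the end-on delay.  The alternative — axes
frozen toward the bat's start pose — makes the projected spacing at
classification time depend on the whole approach trajectory, in which case a
200 microsecond distractor viewed at 60 degrees presents exactly 100
microseconds and the desired target viewed obliquely presents less; no
searcher could then be right every time, which contradicts the qualitative
behaviour the model is meant to reproduce.  Fixed axes remain available per
target (and are what `projected_glint_delay()`'s aspect geometry is tested
on); the choice is flagged here because the source material does not state
how target aspect behaves during approach.

Preset scenes (`single`, `five`, `eight`, `twenty`, `grid90`) follow the
published layouts qualitatively — target counts, spacing sets, and exactly
one 100 microsecond target each — but their coordinates are package
constants, not published values, so epoch counts are not comparable run for
run.  Random scenes draw positions uniformly (minimum separation 0.4 m,
arena 5 m by ~4 m) and spacings from
{30, 50, 200, 300, 500, 1000, 2000} microseconds plus exactly one desired
target.

## What the simulations do and do not show

Everything here is synthetic and deliberately simple: no spreading loss or
atmospheric absorption, no transmit/receive directionality, no clutter,
stationary targets, ideal impulse-like glints, white noise.  Passing tests
therefore show that the receiver implements the SCAT relations correctly and
that the closed loop of estimation and control is stable and selective under
those idealisations — not that the pipeline would perform identically on
real echoes, where lowpass filtering with range, off-axis colouration and
clutter all interact with the null representation.  Problem sizes were
chosen to keep a full check (100 random scenes of 5 to 20 targets, plus the
receiver sweeps) comfortably on one CPU core: a scene search runs a few
seconds; the receiver analyzes one echo in tens of milliseconds.

## Numerical notes

- FFT segments are padded past the channel impulse response (8 integration
  times) so the circular transform cannot wrap the sweep tail onto the
  segment start; without the padding the broadcast's low-frequency event
  times are corrupted.
- Crossing times are only taken from genuine upward crossings; a segment
  already above threshold at its first sample is a cropped echo and carries
  no usable onset.
- Reflections whose delay would overlap the emission (under 0.3 ms) are not
  used for tracking.
- Ties between equally near candidates break toward the lower target id;
  ties between equally prominent nulls resolve toward lower frequency via
  the scan order of the peak finder.
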