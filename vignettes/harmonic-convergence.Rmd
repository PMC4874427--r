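---
title: "Detecting harmonic convergence in paired flight tones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting harmonic convergence in paired flight tones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flighttones)
```

## The problem

Mosquitoes advertise themselves acoustically: the beating wings produce a
flight tone with a strong fundamental (the wing-beat frequency) and
successively weaker harmonic overtones at integer multiples of it. When two
mosquitoes fly within earshot of each other they can actively modulate
their wing-beat frequencies so that an overtone of one approximately
coincides with an overtone of the other — *harmonic convergence*.  In
*Aedes aegypti* males beat their wings roughly 50% faster than females, so
the classic meeting point is the male second and female third harmonic,
i.e. a fundamental-frequency ratio near 3:2; interactions at other small
integer ratios (1:1, 5:4, 4:3, 5:3, 2:1) occur as well, and male–male
pairs interact at the fundamental itself.

Because both sexes occupy overlapping bands of frequency space, apparent
convergence can also arise by chance.  Distinguishing an active behaviour
from coincidence requires (i) frequency traces of each individual at high
time resolution, (ii) an explicit, parameterised definition of a
"convergence event", and (iii) a null model for what non-interacting pairs
look like.  This package implements all three, plus a seeded synthetic
flight-tone simulator used to validate the whole pipeline against known
ground truth.

## Instantaneous frequency extraction

Each mosquito is recorded on its own audio channel (40 kHz sampling in the
standard tethered-pair set-up).  `track_fundamental()` recovers the
instantaneous fundamental $\omega_i(t)$ per channel in two passes:

1. **Coarse ridge tracking.**  A short-time Fourier transform (Hann
   window, default 0.25 s, hop 0.05 s) finds the strongest spectral peak
   inside a sex-specific search band (males 550–900 Hz, females
   350–600 Hz by default), with parabolic interpolation for sub-bin
   accuracy.  If no window contains a clear in-band peak the function
   refuses with a "no flight tone" error.
2. **Analytic-signal demodulation.**  The waveform is demodulated against
   the interpolated ridge and low-pass filtered with a zero-phase
   (forward–backward) Butterworth filter at `relative_bandwidth`
   (default 0.15) times the tracked frequency.  This realizes a
   time-varying band-pass centred on the moving fundamental and yields its
   band-limited analytic signal; the instantaneous frequency is the scaled
   derivative of the unwrapped phase, at the full audio rate.

The raw phase-derivative IF is then median-filtered over 5 ms and
low-pass filtered at 50 Hz — wing-beat modulation is orders of magnitude
slower than the audio rate, and the unsmoothed phase derivative is
dominated by wideband noise.  Half a coarse window at each record end and
around every flight gap is marked invalid (filter transients), as is any
sample where tracking leaves the search band.  Flight-cessation gaps are
found by `detect_flight_gaps()`: samples whose short-time RMS envelope
stays below 10% of the record's median envelope for at least 50 ms.

The filter parameters are deliberately exposed in `filter_spec()` rather
than hard-coded: the coarse window trades ridge stability against
responsiveness, and the relative bandwidth must stay below 0.5 so the
pass band cannot reach the second harmonic.

## Ratio series and the event definition

For a pair of fundamental traces the instantaneous ratio is taken **per
sample with the lower frequency as the denominator**
(`ratio_series()`), so $r(t) \ge 1$ always.  The per-sample convention
matters for male–male pairs, whose traces cross: it keeps 1:1 convergence
representable, and it makes the series exactly symmetric in its
arguments.  For non-crossing opposite-sex traces it coincides with the
obvious orientation.  `separation_series()` gives the companion quantity
$|f_a - f_b|$, the natural coordinate for male–male interactions at the
fundamental.

Convergence events are segmented with a piecewise aggregate approximation
(PAA): the ratio series is reduced to means of consecutive frames of
length $w$, each frame gets a binary state per target ratio according to
whether its mean lies in the tolerance band $(p/q)(1 \pm \delta)$, and
in-band runs are turned into events using a minimum duration $\tau$ and a
minimum separation $\Delta\tau$.  The working parameters are $w = 0.5$ s,
$\delta = 1\%$, $\tau = 1$ s, $\Delta\tau = 1$ s; for 3:2 the band is
[1.485, 1.515].

```{r}
tolerance_band(3, 2, delta = 0.01)
```

Several details of this segmentation were genuinely open and are resolved
as follows (each behind a configuration switch in
`detection_config()`):

* **Merge, then threshold.**  In-band runs separated by a gap of at most
  $\Delta\tau$ are merged into one event *before* the $\tau$ threshold is
  applied (`gap_handling = "merge"`; `"discard"` disables merging).  This
  matches the reading that distinct events are those separated by *more*
  than $\Delta\tau$; short mid-event excursions — convergence is rarely
  perfect — do not split an event in two.
* **Invalid frames break runs and are never merged across.**  A frame
  with fewer than half its samples valid (configurable) is treated as out
  of band, and a gap containing such a frame is never bridged: a flight
  gap should not silently glue two events together.
* **Disjoint bands, unique labels.**  The configured ratio set must have
  pairwise disjoint bands at the chosen $\delta$ (true for the default
  set at 1%); overlapping configurations are rejected up front rather
  than tie-broken, so every event carries exactly one ratio label.
* **Frame-level boundaries.**  Event boundaries are reported at frame
  resolution (the PAA grid); the full-resolution samples inside an event
  are recovered with `event_samples()` for downstream metrics.
* **Partial trailing frame kept.**  The PAA's defining formula assumes
  the frame length divides the series length; the trailing remainder is
  averaged over the samples it has rather than dropped, so up to $w$ of
  signal is never silently discarded.

The default ratio set for opposite-sex pairs is
{1:1, 5:4, 4:3, 3:2, 5:3, 2:1} and {1:1} for male–male pairs
(`mf_ratio_set()`, `mm_ratio_set()`).  7:6 is omitted by default — the
harmonics that would have to coincide are too high to carry useful
acoustic energy — but can be added through the `extra` argument.

## The non-interacting null

`make_artificial_pairs()` builds the randomization null: lone recordings
of the two groups are cross-combined, uniformly without replacement, into
"artificial pairs" that cannot have interacted, and subjected to exactly
the same ratio and event analysis.  Active convergence shows up as
integer-ratio peaks in the pooled ratio distribution of live pairs that
are absent from the artificial-pair distribution.

`cohort_ratio_distribution()` pools pairs with **equal weight** by
default (each pair's own density is averaged), so a long recording cannot
dominate the cohort; `weighting = "pooled"` lumps all samples instead.
The default bin width is 0.005 in ratio units.

## Overlap and local variability

`windowed_histograms()` plus `overlap_series()` quantify convergence as
shared probability mass: per non-overlapping window (1 s) the valid
samples of a chosen harmonic are histogrammed at 1 Hz resolution on a
shared integer-aligned grid (edges at multiples of the bin width starting
from 0 — the resolution is standard, the alignment a fixed convention),
normalized, and compared through the histogram intersection

$$\alpha = \sum_{i=1}^{m} \min(a_i, b_i),$$

with $m$ the number of bins.  $\alpha \in [0, 1]$ is symmetric, equals 1
for identical histograms and 0 for disjoint ones; a rising $\alpha(t)$ is
the waterfall signature of a convergence episode.

`local_cv()` measures short-time variability as
$c_v(t) = \sigma(t)/\mu(t)$ over a centred rectangular sliding window of
0.25 s.  The sample (n−1) standard deviation is used here and in the
cohort statistics.  $c_v$ is exactly invariant under scaling of the trace,
which makes individuals with very different mean wing-beat frequencies
comparable.  `cohort_flight_stats()` separates within-recording
dispersion ($\sigma_\mathrm{intra}$: the mean of per-recording SDs, with
the mean within-recording IQR as a robust companion) from
between-individual dispersion ($\sigma_\mathrm{inter}$: the SD of
per-recording means).

## The synthetic flight-tone simulator

No pair recordings ship with the package, so validation rests on a
simulator whose defaults emulate the published summary statistics of
tethered *A. aegypti*: lone males at a 691.2 Hz baseline with 11.1 Hz
within-recording dispersion, lone females at 479.8 Hz with 9.7 Hz
(`lone_male_profile()`, `lone_female_profile()`); between-individual
baseline spread (90.5 / 31.3 Hz) is added when simulating cohorts
(`simulate_lone_cohort()`).

The within-recording wander is a **band-limited mean-reverting Gaussian
process**: a discrete-time Ornstein–Uhlenbeck process around the
baseline, low-pass filtered at 25 Hz and rescaled to the requested
stationary standard deviation.  Three choices deserve justification:

* *Mean reversion* makes the lone-flight frequency distribution
  approximately normal around a stable baseline, which is what lone
  tethered mosquitoes show.
* *The reversion rate (default 20/s, i.e. a 50 ms correlation time)* is
  the one parameter no published summary pins down.  It was fixed by a
  design requirement of the null model, before the test suite was
  written: wing-beat wander is fast, and a non-interacting pair must
  essentially never hold a ±1% band for a full second by chance.  At slow
  reversion (correlation times of half a second) a simulated
  non-interacting pair drifts through the 3:2 band slowly enough to
  produce spurious "events" in most 60 s runs, which contradicts the
  defining property of the null; at 20/s the Monte-Carlo spurious-event
  probability is below 1% per minute.  Real lone-pair data show smooth
  ratio distributions without integer-ratio peaks, so the fast-wander
  regime is the realistic one.
* *Band-limiting at 25 Hz* reflects that wing inertia caps how fast the
  beat frequency can move; an unfiltered OU process has a Lorentzian
  spectral tail whose power above any IF-smoothing cutoff is
  unrecoverable by construction, which would make round-trip validation
  measure the generator's unphysical tail rather than the tracker.

Scripted convergence (`convergence_script()` + `simulate_pair()`) steers
one partner (configurable to both) so the pair ratio approaches the
scripted $p\!:\!q$ along a linear blend completing at
$3\,\tau_\mathrm{ramp}$ (default ramp constant 0.5 s) and then holds
within a residual jitter fraction of it — convergence is rarely perfect,
and the default residual of 0.3% (clamped, mean-reverting) keeps scripted
events imperfect but inside the 1% detection tolerance.  The linear
blend, rather than an asymptotic exponential, gives a hard containment
guarantee after the ramp, which the test suite asserts on every run.
Because the approach is gradual, the generator logs, per event, both the
steering interval and the *realized in-band interval* computed from the
constructed ratio; the latter is the ground truth detectors are judged
against.

`render_waveform()` turns a frequency trace into audio as
$\sum_k a_k \cos\!\big(2\pi k \int \omega\big)$ with default amplitudes
$1/k$ for $k = 1..5$ (overtones are successively weaker; exact amplitudes
are not critical to frequency analysis), optional white noise, silence in
flight gaps, and a Nyquist guard for the highest harmonic.  Traces are
generated at a 1 kHz control rate and interpolated to the audio rate —
wing-beat modulation lives far below either.

### What the simulator does and does not emulate

It reproduces the published dispersion structure (within/between
recordings), flight gaps, harmonic stacking, scripted convergence with
imperfect residuals, and additive recording noise.  It does **not**
emulate amplitude modulation, frequency "hunting" dynamics around a
partner, non-Gaussian wander, microphone cross-talk between channels, or
any feedback law by which real pairs negotiate convergence — steering is
imposed, not emergent.  Passing tests therefore demonstrate that the
pipeline measures what it claims on signals with known structure of
realistic scale; they do not certify behavioural conclusions about real
recordings.

A related honest limitation of the bundled null suite: its artificial
pairs are simulated at the cohort-mean baselines, so it isolates
within-recording wander.  When baselines are drawn with the full
between-individual spread, a predictable fraction of non-interacting
pairs has a *baseline* ratio lying inside some ±1% integer band and
dwells there indefinitely — such pairs are indistinguishable, over one
minute, from genuine convergence at the level of the ratio series alone.
In real data this is exactly why the population-level comparison (peaks
in the pooled distribution, live versus artificial) carries the
inferential weight, rather than any single pair's time-in-band.

## Numerical choices and degenerate inputs

* Tolerance bands are computed as $(p/q)(1 \pm \delta)$ in floating
  point; tests compare them at $10^{-12}$, i.e. beyond printed precision.
* PAA frame means are exact frame averages (conservation: when the frame
  count divides the length and all samples are valid, the mean of the
  reduction equals the mean of the series; reapplying the same framing is
  the identity).
* The moving statistics in `local_cv()` use exact moving sums
  (convolution, not cumulative-sum differencing) with the variance
  clipped at zero before the square root.
* Degenerate inputs fail loudly: empty recordings, all-silent audio
  (whole-record gap plus a warning), recordings without valid samples
  (excluded from cohort statistics with a warning), single-recording
  cohorts ($\sigma_\mathrm{inter}$ undefined), `w` longer than the series
  (single frame, warning), overlapping scripted events or tolerance
  bands (errors).
* All seeded entry points restore the caller's RNG state, so identical
  seeds give bit-identical outputs regardless of the surrounding
  programme.

## Problem sizes used in validation

The test suite and bundled validation scenarios are sized to what the
analysis actually needs: event-detection and null-model checks run on
60 s traces at the 1 kHz control rate (20 scripted pairs, 50 artificial
pairs), audio-rate extraction checks on 2–10 s clips at 40 kHz, and
oracle equivalences on 100 randomized small instances.  These sizes were
chosen as the smallest at which the measured quantities are stable; all
parameters scale to full-length cohorts unchanged.

## A worked example

```{r example}
sc <- convergence_script(3, 2, onset_s = 10, duration_s = 6)
pr <- simulate_pair(lone_male_profile(duration_s = 30),
                    lone_female_profile(duration_s = 30), sc, seed = 42)
rs <- ratio_series(pr$trace_a, pr$trace_b)
ev <- detect_events(rs, detection_config())
ev
glance(ev)
```

The detected interval can be compared against the simulator's realized
in-band truth, `pr$truth`, and visualised with
`autoplot(rs, bands = detection_config()$bands, events = ev)`.
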