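# flighttones

Quantitative detection and characterisation of **harmonic convergence**
between the flight tones of paired mosquitoes.

A mosquito's beating wings emit a tone with a high-energy fundamental (the
wing-beat frequency, roughly 690 Hz for male and 480 Hz for female tethered
*Aedes aegypti*) and successively weaker harmonics at integer multiples of
it. Interacting pairs can actively modulate their wing beats so that the
harmonics of one nearly coincide with those of the other — e.g. the male
second and female third overtone meeting at a fundamental ratio of 3:2.
Because both sexes occupy overlapping frequency bands, convergence can also
occur by chance; this package provides the full analysis chain needed to
detect convergence events robustly and to benchmark them against a
non-interacting null.

The pipeline, with each stage a tibble-in / tibble-out function:

1. **Instantaneous-frequency extraction** (`track_fundamental()`): coarse
   STFT ridge tracking of the fundamental inside a sex-specific search
   band, followed by a time-varying band isolation (ridge demodulation +
   zero-phase Butterworth low-pass) and the analytic-signal phase
   derivative, giving ω(t) at the full audio rate; flight-cessation gaps
   are masked (`detect_flight_gaps()`).
2. **Pairwise series** (`ratio_series()`, `separation_series()`): the
   instantaneous ratio r(t) = max(ω_a, ω_b) / min(ω_a, ω_b) ≥ 1, and the
   absolute separation |ω_a − ω_b|.
3. **Event detection** (`paa_reduce()`, `detect_events()`): the ratio
   series is reduced by a piecewise aggregate approximation (frame means,
   window *w*), each frame gets a binary state per integer ratio p:q
   according to the tolerance band (p/q)(1 ± δ), and in-band runs are
   merged across gaps ≤ Δτ then thresholded at a minimum duration τ.
   Working parameters: *w* = 0.5 s, δ = 1% (3:2 band = [1.485, 1.515]),
   τ = 1 s, Δτ = 1 s.
4. **Null model** (`make_artificial_pairs()`): lone recordings are
   randomly cross-paired without replacement into "artificial pairs" whose
   pooled ratio distribution (`cohort_ratio_distribution()`) shows what
   chance alone produces.
5. **Convergence metrics** (`windowed_histograms()`, `overlap_series()`,
   `local_cv()`): per-window histogram intersection
   α = Σᵢ min(aᵢ, bᵢ) ∈ [0, 1] between the two subjects' frequency
   distributions, and the local coefficient of variation
   c_v(t) = σ(t)/μ(t) over a 0.25 s sliding window.
6. **Cohort summaries** (`summarize_cohort()`, `aggregate_durations()`,
   `cohort_flight_stats()`): event counts and rates per recording and per
   unique pair; within- (σ_intra) versus between-recording (σ_inter)
   frequency dispersion.

A seeded synthetic flight-tone simulator (`simulate_trace()`,
`simulate_pair()`, `render_waveform()`) generates single and paired traces
— band-limited mean-reverting wander around cohort-typical baselines, with
scripted convergence episodes and rendered harmonic audio — and is used
throughout the tests to validate the pipeline against known ground truth.

## Worked example

Simulate a male–female pair with one scripted 3:2 convergence episode,
then detect it:

```r
library(flighttones)

sc <- convergence_script(3, 2, onset_s = 10, duration_s = 6)
pr <- simulate_pair(lone_male_profile(duration_s = 30),
                    lone_female_profile(duration_s = 30), sc, seed = 42)
rs <- ratio_series(pr$trace_a, pr$trace_b)
ev <- detect_events(rs, detection_config())
ev
#> # A tibble: 1 × 6
#>   label     p     q start_s end_s duration_s
#>   <chr> <int> <int>   <dbl> <dbl>      <dbl>
#> 1 3:2       3     2      11  16.5        5.5
```

The detector reports one event at the 3:2 ratio spanning 11–16.5 s: the
steering starts at 10 s but the ratio only enters the ±1% band part-way
through the approach ramp, and the simulator's ground truth
(`pr$truth`) puts the realized in-band interval at 11.2–16.3 s — the
frame-resolution boundaries are within half a PAA window of it.
`glance(ev)` summarises the events (here: 1 event, 5.5 s total
convergence time), and
`autoplot(rs, bands = detection_config()$bands, events = ev)` draws the
ratio series with the tolerance bands and detected spans.

Cohort-level statistics recover the generator's dispersion parameters:

```r
coh <- simulate_lone_cohort(27, lone_male_profile(duration_s = 20),
                            sigma_inter_hz = 90.5, seed = 14)
glance(cohort_flight_stats(coh))
#>   n_recordings  mu mu_min mu_max sigma_intra sigma_inter iqr_intra
#> 1           27 737    576  883.4        11.1        81.6      14.8
```

σ_intra ≈ 11 Hz (within-recording wander) is an order of magnitude smaller
than σ_inter ≈ 82 Hz (between-individual spread), the structure that makes
the randomized-pair null informative.

A thin command-line front end over the same functions is installed at
`inst/cli/flighttones` with `simulate`, `extract`, `pair` and `cohort`
subcommands (WAV in, CSV/JSON out); detection flags `--delta`, `--tau`,
`--delta-tau` and `--paa-window` override the configuration one-to-one.

## Vignette

`vignettes/harmonic-convergence.Rmd` documents the model and the design
decisions: the event definition and its parameters, the ratio and
weighting conventions, the overlap metric, the synthetic generator's
assumptions and calibration, numerical edge cases, and known limitations.
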