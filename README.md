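# gyrostep

Walking detection and step counting from smartphone gyroscope traces,
for researchers in mobile sensing, pedestrian dead reckoning and digital
health who need a transparent, scriptable alternative to black-box
pedometer apps — one that works when the phone's placement is arbitrary
and changes mid-recording.

## The method

The input is a uniformly sampled 3-axis angular-velocity trace
(rad/s, nominally 20 Hz). A sliding window of N = 64 samples
(span (N−1)/fs = 3.15 s) advances by 1.2 s, and per window:

1. **Sensitive axis** — the axis with the largest summed absolute angular
   velocity, `argmax_a Σ|ω_a(i)|`, carries the gait signal best whatever
   the placement.
2. **Spectrum** — the radix-2 FFT amplitude `|X(k)|` of that axis; bin k
   sits at `k·fs/N` Hz, so the human walking band 0.6–2 Hz holds exactly
   five bins (0.625–1.875 Hz) and the sub-walking band holds bin 1.
3. **Decision** — walking iff the walking-band mean amplitude ω̄c beats
   the sub-walking mean ω̄0 **and** exceeds the threshold 10 (raw DFT
   units). The first condition rejects slow swings such as placement
   switches; the second rejects weak jitter such as typing while standing.
4. **Counting** — each walking window adds 1.2 s of walking time; its
   cadence is the maximiser of the quartic
   `A = af⁴ + bf³ + cf² + df + e` interpolated through the five band
   bins, smoothed across windows by `f̄w ← 0.8·f̄w + 0.2·f̂w`; steps
   accumulate as `c += 1.2·f̄w`. No per-step event detection anywhere.

Evaluation uses duration-based precision/recall for detection and the
symmetric accuracy `A = (1 − |s_e − s_a|/s_a)·100` for counting. A
seeded synthetic generator (walks with harmonics, stills, typing,
placement-switch bursts) provides labelled fixtures with exact ground
truth.

## Worked example

```r
library(gyrostep)

res <- generate_trace(scripted_scenarios()$continuous_walk, seed = 1)
fit <- gyrostep(res$trace)
fit
#> Gyroscope walking detection and step counting
#>   windows analysed : 98 (N = 64, hop = 24, fs = 20 Hz)
#>   walking windows  : 98
#>   walking duration : 117.6 s
#>   cadence (smoothed): 1.250 Hz
#>   step count       : 147 (raw 147.00)

score_count(fit$steps, res$true_steps)
#> step accuracy = 98.00%  (estimated 147, actual 150)
```

The scenario is 120 s of walking at 1.25 Hz, i.e. 150 true steps. All 98
windows are classified walking and the cadence is recovered exactly (the
1.25 Hz fundamental falls on a spectral bin). The counter credits 1.2 s
per window, so walking time is 117.6 s rather than 120 s — the first
window spans 3.15 s but contributes one slide — giving 147 steps, a 2%
undercount that shrinks with bout length. `summary(fit)` adds the
predicted segments, `plot(fit)` shows band amplitudes against the
threshold and the cumulative count, and `coef(fit)` returns
steps/walking time/cadence.

The same pipeline is available from the shell:

```sh
exec/gyrostep simulate --scenario continuous_walk --seed 1 --out-trace t.csv --out-truth truth.csv
exec/gyrostep count --input t.csv --out log.csv
#> steps=147 walking_seconds=117.6
exec/gyrostep detect --input t.csv --out seg.csv
exec/gyrostep eval --pred seg.csv --truth truth.csv
```

`detect`/`count` accept `--threshold`, `--alpha`, `--reset-on-gap`,
`--deg` (deg/s input) and a YAML `--config` file; flags override the
file, which overrides the defaults above.

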