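---
title: "How gyrostep detects walking and counts steps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How gyrostep detects walking and counts steps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 5)
library(gyrostep)
```

# The problem

A smartphone carried without constraint — in a hand, a trouser pocket,
swapped between the two mid-walk — still rotates cyclically with every gait
cycle, and its gyroscope records that rotation as 3-axis angular velocity
oscillating around zero. `gyrostep` exploits two robust properties of this
signal: the oscillation's fundamental frequency is the cadence (steps per
second), which for human walking lies between 0.6 and 2 Hz, and the
*frequency-domain* signature survives changes of placement that badly
distort time-domain features such as peaks or zero crossings. The package
answers two questions per recording: *when* was the holder walking, and
*how many steps* were taken — the latter indirectly, as walking duration
times cadence, with no per-step event detection at all.

# The detection rule

The trace is analysed in sliding windows of $N = 64$ samples at
$f_s = 20$ Hz (span $(N-1)/f_s = 3.15$ s, slightly longer than one gait
cycle), advancing by 24 samples = 1.2 s, about the duration of one step.
For each window:

1. **Sensitive axis.** The axis $a$ maximising
   $\sum_{i=1}^{N} |\omega_a(i)|$ is selected. Gyroscope noise dominates
   when rates are small and is negligible when they are large, so the
   loudest axis carries the best-conditioned copy of the gait signal;
   using a single real axis rather than the 3-D magnitude keeps the
   oscillation's structure intact. Ties break as x < y < z.
2. **Spectrum.** The unnormalized DFT magnitude
   $|X(k)| = \left|\sum_{n=0}^{N-1} \omega(n) e^{-j 2\pi nk/N}\right|$ is
   computed by radix-2 FFT; bin $k$ sits at $k f_s / N$ Hz, so at the
   defaults the walking band 0.6–2 Hz contains exactly the five bins
   $k = 2..6$ (0.625–1.875 Hz) and the sub-walking band contains bin 1
   (0.3125 Hz).
3. **Decision.** With $\bar\omega_c$ the mean amplitude over the five
   walking-band bins and $\bar\omega_0$ the mean over the sub-walking band,
   the window is *walking* iff both
   $\bar\omega_c > \bar\omega_0$ and $\bar\omega_c > 10$
   (strict inequalities; ties are non-walking). The first condition rejects
   slow large motions — a placement switch is a smooth sub-0.6 Hz swing
   whose energy lands below the band — and the second rejects weak
   narrowband motion such as typing while standing, which can satisfy band
   dominance at tiny amplitude.

## Numerical and convention choices

* **Amplitude units.** The threshold of 10 applies to raw $|X(k)|$ of a
  rad/s signal over a 64-sample window — no $1/N$, no one-sided doubling,
  no taper or detrending. Any alternative scaling must rescale the
  threshold (`detection_config(amp_threshold=)`); a `--deg` ingest flag
  converts deg/s logs.
* **DC bin.** Excluded from $\bar\omega_0$ by default: at rest it carries
  the gyroscope's constant bias, not motion energy (`include_dc` restores
  it).
* **Hop of 24 samples.** The 1.2 s slide covers 25 sample *instants*
  inclusive — the same endpoint convention by which 64 samples span
  3.15 s — so the window must *advance* by 24 samples to move exactly
  1.2 s. This keeps the per-window walking-duration increment equal to the
  slide.
* **Uniform sampling is enforced, not repaired.** The bin→Hz map assumes
  $f_s$ exactly, so `read_trace()` rejects non-uniform logs and
  `resample_trace()` (linear interpolation) is an explicit user step.
* **Segment attribution.** For reporting, each window's label is attributed
  to its trailing 1.2 s slide interval — the same span the counter credits
  — and adjacent equal labels are merged. Because a window containing only
  ~1.5 s of energetic walking still passes both conditions, predicted
  boundaries trail true walk endings by one to two slides; the evaluation
  module's duration-based precision/recall makes such edge effects visible
  rather than hiding them.

# Cadence estimation and step counting

Each walking window contributes 1.2 s of walking duration. Its cadence is
estimated from the same spectrum: the five walking-band pairs
$(f_k, |X(k)|)$ are interpolated by the quartic
$A = af^4 + bf^3 + cf^2 + df + e$ (five points, five coefficients — the
"fit" is exact interpolation, solved as a 5×5 Vandermonde system), and the
estimate $\hat f_w$ is the frequency maximising $A$, located among the real
roots of $A'$ plus the interval endpoints.

**Maximisation interval.** The search runs over the intersection of the
walking band with the span of the five fit nodes, i.e. [0.625, 1.875] Hz at
the defaults. Outside the nodes the quartic *extrapolates*: for a
single-bin spectrum peaked at 1.25 Hz the extrapolated value at 2.0 Hz is
about 2.1× the true peak, so an unrestricted band-wide argmax would jump to
the band edge. Restricting to the node hull removes the extrapolation
artefact while changing nothing for spectra whose peak is interior.

**A known, quantified bias.** Exact interpolation through five points has a
second artefact that no argmax interval can remove: when the quintuple is
spike-like (one dominant bin, near-zero neighbours), the interpolant's
maximum sits at the spiked node only in the symmetric cases (bins 2, 4, 6).
For a spike at bin 3 (0.9375 Hz) the Lagrange basis polynomial overshoots
to ≈1.15 at ≈0.8355 Hz, an intrinsic bias of ≈0.1 Hz; a pure-sinusoid walk
at ~0.9–1.05 Hz produces exactly such quintuples, and the test suite
freezes this behaviour against an interpolation-free grid-search oracle.
Real gait spectra have broader peaks, which keeps the bias small in
practice, but synthetic single-tone fixtures near bin 3 will show cadence
errors up to ~0.15 Hz (always well within one bin width, 0.3125 Hz).

The raw estimates are smoothed across windows by an exponentially weighted
moving average,
$\bar f_{w,i} = \alpha \bar f_{w,i-1} + (1-\alpha)\hat f_{w,i}$ with
$\alpha = 0.8$, initialised to the first walking window's $\hat f_w$. Steps
accumulate *incrementally*, $c \mathrel{+}= 1.2\,\bar f_{w,i}$ per walking
window, rather than as a final product $t \times \bar f_w$ — the final
product would retroactively apply the latest cadence to all earlier
walking, which is not what a real-time recursive counter does. The count is
kept real-valued and rounded only for reporting. By default $\bar f_w$
persists across non-walking gaps within a trace (nothing in the update rule
resets it); `counting_config(reset_on_gap = n)` forgets it after `n`
consecutive non-walking windows, so a fresh bout re-initialises.

Degenerate case: if all five amplitudes are equal the quartic is flat and
carries no peak information; the central bin frequency (1.25 Hz) is
returned with a `degenerate` flag.

# Evaluation metrics

Detection is scored by *duration*, not events: over the common time span of
prediction and truth, $TP$/$FP$/$FN$ are seconds of
correctly/incorrectly/missed walking time, and
$P = 100\,TP/(TP+FP)$, $R = 100\,TP/(TP+FN)$. Counting accuracy is
$A = (1 - |s_e - s_a|/s_a) \times 100$ — symmetric in over- and
under-counting, and deliberately allowed to go negative when the error
exceeds the actual count.

# The synthetic generator

`generate_trace()` renders an activity script into a labelled trace. The
walk model is a fundamental sinusoid at the cadence plus 2nd/3rd harmonics
(relative weights 0.3/0.15 — gait spectra show clear secondary peaks),
distributed over axes by an energy mix (default 0.2/0.6/0.2, a
pocket-like placement with y dominant), plus white Gaussian noise and a
0.02 rad/s constant bias. The default amplitude of 6 rad/s puts
$\bar\omega_c$ at 3–5× the threshold — an energetic but realistic pocket
signal, firmly in the detectable regime. Stills are bias + noise; typing is
a 0.3 rad/s narrowband jitter near 1.1 Hz (band-dominant but
sub-threshold); a placement switch is 4th-order-Butterworth low-passed
noise (0.4 Hz cutoff) rescaled to 2.5 rad/s — a smooth, large,
sub-walking-frequency swing with no walking-band peak.

What the generator *does not* emulate — and hence what green tests do not
demonstrate about real data: cadence variability within a bout, asymmetric
or impaired gait, gradual placement drift, flicker/bias-instability noise,
and the broadband harmonic spread of real strides. Its spectra are
*spikier* than real gait spectra, which is the hard case for the quartic
estimator (see above), so synthetic cadence errors if anything overstate
the real ones at near-bin frequencies.

# Problem sizes and reproducibility

The suite and the acceptance script work at desk scale: traces of 20–150 s
(a few hundred to 3000 samples, up to ~120 windows), 1000 random
quintuples for the argmax cross-check, DFT oracles at $N \le 64$; every
stochastic fixture is generated from a fixed seed and the generator is
bit-reproducible given it. `scripts/acceptance.R` recomputes the analytic
identities, oracle agreements, cadence/step recovery and mixed-scenario
detection scores from scratch at any seed.

# Known limitations

* Cadences at the band edges (< 0.7 or > 1.8 Hz) collide with the node
  hull: estimates clamp at 0.625/1.875 Hz.
* Walking-duration credit starts one full window late (the first window
  contributes 1.2 s although it spans 3.15 s), an undercount of ~2% on a
  120 s bout.
* The detector is binary; running, cycling or stair climbing are simply
  whatever side of the two conditions their spectra fall on.
* Thresholds assume the documented amplitude scaling; recordings in other
  units or at other window lengths need recalibration, not just
  resampling.
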