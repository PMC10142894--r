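---
title: "Event-locked HRV analysis of nodding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-locked HRV analysis of nodding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodeffect)
```

## The scientific question

Nodding while listening — to agree, or to mark understanding — appears to
feed back on the nodder's own autonomic state. The design this package
analyses compares three lecture-watching conditions: no nodding video,
a nodding video with spontaneous (not forced) nodding, and a nodding video
with cued (forced) nodding. The outcome is heart-rate variability: pNN50,
the proportion of adjacent heartbeats whose RR intervals differ by more
than 50 ms, rises with parasympathetic (restful) activity and falls with
arousal. The question is whether the minute following a nod shows a change
in pNN50 beyond the participant's own session-wide drift, and whether that
change differs between spontaneous and forced nods.

## The per-nod statistic

For each continuous recording we compute a sliding pNN50 series: a trailing
window of `window_beats = 100` beats (roughly one minute at typical resting
heart rates), emitted at every beat and anchored at the window's *end*. The
anchoring matters: the sample at the moment of a nod summarises only the
minute *before* it, while the sample one lag later contains the post-nod
minute.

For a nod at time $t$ with lag $t_0$ (default 60 s), the event-locked slope
is

$$N_s = \frac{\mathrm{pNN50}(t + t_0) - \mathrm{pNN50}(t)}{\Delta t},$$

where $\mathrm{pNN50}(x)$ is the latest valid sample at or before $x$
(last-observation anchoring, no interpolation — interpolating would blur
the "window excludes / includes the event" semantics), and $\Delta t$ is
the actual time between the two anchored samples. Anchors fall on beat
times, so $\Delta t = t_0$ whenever the anchors align with the nominal
times and differs by at most one beat otherwise. We divide by the actual
spacing rather than the nominal lag because only that choice makes $N_s$ a
true two-point slope: a series that is exactly linear with slope $b$ gives
$N_s = b$ at every anchor on any beat grid, and adding a global ramp
$c \cdot t$ to the series shifts $N_s$ by exactly $c$. Both identities are
enforced to $10^{-12}$ in the test suite, and both would fail at order
(beat length)/$t_0$ with a nominal-lag denominator.

The session trend $N_{all}$ is the ordinary-least-squares slope of the
whole recording's valid pNN50 samples against time. The **nodding effect**
is

$$N = N_s - N_{all},$$

in units of s$^{-1}$. Subtracting $N_{all}$ removes the participant's own
drift (for example a slow rise with sleepiness), so negative $N$ means
pNN50 fell faster than the participant's trend after the nod — read as
increased arousal. Each lecture half is a separate recording with its own
$N_{all}$, because the rest break between halves interrupts the signal.

The matched **baseline** applies the identical statistic at probe times
where the participant did not nod: every valid sample time $s$ (optionally
a strided subset) with no nod in $[s - g, s + t_0]$, with guard
$g = t_0$ by default so that neither anchor window can contain a nod.

Choices the study description left open, resolved here:

* Nods closer than $t_0$ to each other each contribute their own effect
  value (the forced condition would otherwise lose nearly all its nods).
* Nods inside sleep-annotated spans are kept by default
  (`sleep_policy = "include"`), since the annotation's role in the original
  design was descriptive; `"exclude"` is available.
* Baseline probes default to every valid beat sample (`baseline_stride_s =
  NULL`), matching the "instantaneous values of all intervals" reading.
  Neighbouring per-beat probes are strongly dependent, which is harmless
  for describing the distribution but matters when the values enter a rank
  test that assumes independent observations; the simulation studies below
  therefore set a stride of one lag (60 s) or more, and users feeding
  `compare_conditions()` should do the same.

## Group comparison

The three pooled samples — baseline trend values, spontaneous-nod effects
(from both the no-video and video conditions, both halves), and forced-nod
effects — are compared with a tie-corrected Kruskal–Wallis test
(mid-ranks; $H$ referred to $\chi^2_{k-1}$), followed, only when the
omnibus test is significant (protected LSD), by pairwise least-significant-
difference comparisons. The LSD is computed on the pooled mid-ranks
(Conover's procedure) with the pooled within-group rank variance on
$N - k$ degrees of freedom; a raw-scale option exists
(`on_ranks = FALSE`). The scale of the original report's pairwise statistic
is not recoverable without the raw data, so the rank scale was chosen as
the one consistent with applying LSD to the same samples as the rank-based
omnibus test. Every nod is treated as an independent sample, as in the
original pooling of 70 and 1339 nods; the per-session counts are carried in
the report so the clustering is visible.

## The synthetic-session generator

No participant recordings are deposited anywhere, so validation rests on a
generator whose ground truth is known. It models the tachogram as

$$\mathrm{RRI}_k = \mu + d(t_{k-1}) + A_{LF}\sin(2\pi f_{LF} t_{k-1})
  + A_{HF}\sin(2\pi f_{HF} t_{k-1}) + x_k,
  \qquad x_k = \phi\, x_{k-1} + \varepsilon_k,$$

with beat times the running sum of the intervals, piecewise-linear drift
$d$, and AR(1) noise. Defaults: $\mu = 850$ ms, $\phi = 0.4$,
$\sigma = 30$ ms, $A_{LF} = A_{HF} = 10$ ms at 0.10 and 0.25 Hz — values in
the range reported for seated adults at rest, giving resting pNN50 around
0.15–0.25. Intervals are clamped to [300, 2000] ms (clamps are counted and
reported). Spontaneous nods are a homogeneous Poisson process (0.4/min by
default — sparse, as students rarely nod); forced nods follow the supplied
cue times.

The event coupling is the one knob the study's description cannot supply:
nothing is reported about *how* a nod perturbs RRI dynamics, only how the
derived statistic behaved. Because pNN50 responds directly to
successive-difference variability, the generator multiplies the AR
innovation scale by $1 + \delta$ for `effect_duration_s` (60 s) after each
nod onset, merging overlapping windows. $\delta$ (`effect_delta`) is a free
calibration parameter with analytic control of the ground-truth sign:
$\delta < 0$ suppresses successive differences, lowering pNN50, hence a
negative nodding effect. The magnitude $|\delta| = 0.3$ used in the
validation studies produces mean effects of order $10^{-4}$–$10^{-3}$
s$^{-1}$, the order the original analysis reported; it was fixed once on
that reasoning.

What the generator does *not* emulate: respiratory sinus arrhythmia locked
to real breathing, ectopic beats, sensor dropouts, circadian nonstationarity
beyond linear drift, and person-level heterogeneity (all sessions share one
parameter set unless varied explicitly). Passing the recovery tests
therefore shows the pipeline correctly extracts an effect of this known
form from plausibly noisy RRI streams — not that real nodding has such an
effect.

## Spectral estimation

LF/HF uses a trailing two-minute window. The tachogram's natural time grid
is uneven, so the default estimator is a Lomb–Scargle periodogram evaluated
on an oversampled grid (spacing $1/(4 \times 120)$ Hz) and integrated over
the conventional bands, 0.04–0.15 Hz (LF) and 0.15–0.40 Hz (HF). An
alternative route — cubic-spline resampling to 4 Hz followed by a smoothed,
tapered periodogram — is selectable and agrees with Lomb–Scargle within
about 20% on stationary series (tested). Windows with fewer than 30 beats,
constant tachograms, or vanishing HF power yield invalid samples rather
than errors. For a white-noise tachogram the expected band-power ratio is
the bandwidth ratio $0.11 / 0.25 = 0.44$, which anchors the calibration
test.

## Numerical and validation choices

* pNN50 uses a strict inequality (differences of exactly 50 ms do not
  count) and is reported as a proportion in $[0, 1]$; the effect magnitudes
  above are only coherent on that scale.
* The sliding implementation is cumulative-sum based and is tested for
  exact equality against a naive per-window recount over window sizes
  2–100; artifact-rejection gaps drop the spanning pair from numerator and
  denominator.
* Artifact screening removes beats outside [300, 2000] ms or jumping more
  than 30% from the last accepted beat; removals are enumerated, never
  silent.
* Kruskal–Wallis and the LSD are implemented in the package (the
  field-standard `stats::kruskal.test` serves as an independent
  cross-check in the tests, as does an exact permutation enumeration for
  tiny samples).
* Simulation studies in the test suite use 100 cohorts of 10 sessions per
  condition (15-minute recordings, ~30 nods each) for sign-recovery and 200
  null cohorts of 3 sessions per condition (20-minute recordings, ~10 nods
  each) for type-I calibration; these sizes give stable Monte-Carlo
  estimates while keeping the suite quick to run. Both studies decimate
  baseline probes (60 s and 120 s strides) for the independence reasons
  above.
* All randomness flows through R's RNG: a session is bit-reproducible from
  its parameters and seed, and cohort session seeds derive from one master
  seed.

## Known limitations

Treating every nod as independent ignores within-participant correlation;
a mixed-model re-analysis is out of scope but the per-session counts make
the clustering visible. The chi-square reference for $H$ and the t
reference for the rank LSD are asymptotic; with per-beat (unstrided)
baseline probes the independence assumption is knowingly violated, which is
why the calibration studies stride. The lag $t_0 = 60$ s is a design
constant tied to the 100-beat window, not an estimate of how long a nod's
effect lasts.
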