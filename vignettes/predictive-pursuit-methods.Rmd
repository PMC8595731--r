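---
title: "Predictive smooth pursuit: models, measures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive smooth pursuit: models, measures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predpursuit)
library(dplyr)
```

## The scientific problem

When a tracked target abruptly reverses direction, the smooth pursuit
system does not wait for visual feedback: with a predictable stimulus, eye
velocity starts to fall *before* the reversal. `predpursuit` analyzes this
predictive deceleration in a triangular-waveform ramp paradigm: the target
sweeps 24 deg rightward at a fixed 16 deg/s, then returns leftward at one
of seven velocities (4–28 deg/s). In the *predictable* condition the
leftward velocity is constant within a block (7 blocks x 30 trials); in
the *unpredictable* condition it is drawn at random within each of 5
blocks of 49 trials (each velocity 7 times).

Three per-trial measures quantify the predictive response, all relative to
the right-to-left target reversal at time 0:

* **eye deceleration onset** — when smoothed eye velocity first falls,
  and stays, below 80% of the observer's steady-state velocity (pooled
  mean over the window 700–500 ms before reversal);
* **timing of eye reversal** — when eye velocity crosses 0 deg/s
  (sub-sample linear interpolation);
* **mean eye deceleration** — mean eye acceleration between those two
  events.

The central scientific question is how *stimulus history* (the leftward
velocities of recent trials) and *behavioral history* (the observer's own
recent reversal timings) shape the current trial's reversal timing when
the stimulus itself is unpredictable.

## The history model

The timing of eye reversal on trial $n$ is modeled as

$$T_n = \beta_0 + b_{\mathrm{obs}}
  + \sum_{k=1}^{K} \beta^{\mathrm{stim}}_k V_{n-k}
  + \sum_{k=1}^{K} \beta^{\mathrm{behav}}_k T_{n-k}
  + \varepsilon_n ,$$

with $V$ the leftward target velocity (deg/s), a Gaussian per-observer
random intercept $b_{\mathrm{obs}}$, and i.i.d. Gaussian noise. Fifteen
candidate structures are fitted by maximum likelihood with `lme4`
(stimulus lags 1..k alone; behavior lags alone; both; $k = 1..5$) and
compared by AIC. Maximum likelihood (not REML) is required because the
models differ in their fixed effects. Wald $t$ statistics are reported
with residual degrees of freedom $n - p$ — with ≈2,400 rows and 12
grouping levels the large-sample convention is appropriate and no
Satterthwaite correction is applied. All 15 models are fitted on the row
set of the largest model (all lags to $n-5$ available): a shared row set
is the only choice under which the AIC comparison is well defined.

Histories never cross block boundaries. The first five trials of each
block serve only as predictors (their own timings have incomplete
histories), and rows whose behavior lags point at an excluded or
undetected trial are dropped (complete-case); stimulus lags are always
observable, excluded trial or not.

## What the simulator emulates — and what it does not

The synthetic-data generator is a generative twin of that model plus a
trace-level layer, so every pipeline stage can be checked against known
truth:

* **Stimulus sequences** reproduce both block designs exactly.
* **Reversal timings** follow the history model. Its defaults encode
  the published full-history estimates for this paradigm (intercept
  30.620 ms; stimulus-lag weights −0.096, −0.417, −0.215, 0.034, −0.074
  ms per deg/s; behavior-lag weights 0.078, 0.093, 0.029, 0.001, 0.029).
  The residual SD is not printed anywhere; 32.5 ms is back-derived from
  the reported standard errors (a stimulus-lag SE of ≈0.079 at ≈2,400
  rows with a velocity SD of 8 deg/s implies σ ≈ 32.5 ms, and the
  behavior-lag SEs give the same number). The between-observer intercept
  SD is likewise unreported; 10 ms is a realistic spread that leaves
  observers clearly distinguishable without dominating the residual.
  At block starts, missing lags contribute zero (burn-in rule), mirroring
  the design-matrix convention.
* **Eye traces** hold velocity at `pursuit_gain` times target velocity in
  steady state (gain 0.95 by default; 0.9–1.0 is the normal range for
  foveal ramp tracking), then
  follow a raised-cosine velocity ramp from the rightward steady state to
  the leftward one. The raised cosine is smooth, monotone, and
  analytically invertible: given the trial's true reversal timing and a
  true onset lead drawn uniformly from 100–250 ms, the ramp duration is
  solved so the velocity crosses zero exactly at the true reversal. The
  lead range sits inside the window admitted by the −300 ms exclusion
  bound, so the exclusion logic is exercised from both sides.
* **Artifacts**: white Gaussian position noise (0.05 deg SD) and
  catch-up saccades injected as minimum-jerk position steps (1–3 deg,
  20–40 ms, ~1/s). Minimum-jerk steps guarantee supra-threshold
  acceleration (> 1000 deg/s²) without discontinuities.

The simulator is deliberately not an oculomotor plant model: no pursuit
latency dynamics, no blinks or pupil artifacts, no vertical channel, no
velocity-dependent noise, and the deceleration profile is one fixed
family. Passing tests therefore demonstrate that the *pipeline* recovers
the events and weights that generated the data — not that real eye traces
follow a raised cosine.

## Preprocessing choices

The chain is fixed: central-difference differentiation → 30 Hz low-pass →
saccade detection on filtered acceleration → removal and linear
interpolation in the velocity trace → 40 ms moving average.

* **FIR design.** "80-point FIR with a 30 Hz passband" is realized as an
  order-80 Hamming-window linear-phase low-pass at 1 kHz, normalized to
  unit DC gain. Filtering is zero-phase: the symmetric kernel is applied
  as a single centered convolution with odd-reflection edge padding,
  which realizes exactly the designed magnitude response and adds no
  group delay. Zero phase matters because event *timings* are the primary
  outcome; a causal pass would shift every onset and reversal by the
  filter delay.
* **Saccade criterion.** The acceleration criterion is 1000 deg/s²
  (an acceleration threshold dimensionally requires deg/s²).
  Supra-threshold runs are padded by 10 ms per side and merged when they
  overlap. Interpolation is linear in the velocity domain, and the clean
  acceleration is recomputed from the interpolated velocity.
* **Moving average.** A centered 41-sample boxcar (the odd sample count
  closest to 40 ms at 1 kHz), with shrinking windows at the trace edges
  so no samples are lost. Note that an odd boxcar does not null the
  Nyquist component — alternating ±1 passes at amplitude 1/41.
* **Edges.** Endpoints use one-sided differences. With noisy input the
  one-sided endpoint difference is noise-amplified and the trailing
  ~50 ms of a trace can be flagged as a saccade-like artifact and
  interpolated; the rendered trace window (−1500 to +800 ms) keeps all
  analysis windows far from both edges.
* **Event-stage acceleration.** The mean eye deceleration is computed
  from the derivative of the same moving-averaged velocity on which the
  events are detected, so mean acceleration over [onset, reversal] is
  consistent with the velocity drop between the detected events.

## Event detection and exclusion

The steady-state mean pools all trials of one observer x condition:
observers differ in gain, so per-observer thresholds avoid a systematic
onset bias, while pooling across trials of a condition keeps the
threshold independent of single-trial noise. The onset search starts at
−500 ms (the steady-state window itself must not trigger), and the
"fell below threshold" rule is made noise-robust by requiring the
velocity to stay below threshold continuously until the zero crossing:
the onset is the first sample of the sub-threshold run that contains the
reversal. The reversal is interpolated between the bracketing samples
(sub-millisecond precision; it is the LME response variable), while the
onset is reported at sample resolution — its uncertainty is dominated by
the 40 ms smoothing window anyway.

Trials are excluded when the onset precedes −300 ms (typically a
saccade landing at the anticipated reversal position), when the reversal
follows +100 ms (visual feedback has arrived), or when either event is
undetected; undetected trials are counted separately from the two stated
rules.

## Node (tree) analyses

Because successive reversal timings are positively correlated, naive
multiple regression on lagged timings risks multicollinearity; the node
method instead conditions on a categorical property of a preceding
trial. Per observer x velocity cell, included timings are ranked
ascending; the earliest `floor(0.2 n)` are "UPPER", the latest
`floor(0.2 n)` "LOWER" (stable original-order tie-break, so the
classification is deterministic). Current-trial means are then compared
between trials preceded (at lag 1 or 2) by an UPPER versus a LOWER trial
— or, for stimulus history, by the slowest (4 deg/s) versus fastest
(28 deg/s) velocity — with a paired $t$ test across observers and
Cohen's $d = \bar{d}/s_d$.

The within-subject association between an event measure and target
velocity uses the repeated-observations correlation: both variables are
centered per observer and correlated, with $N - k - 1$ degrees of
freedom ($N$ pairs, $k$ observers) — the analysis-of-covariance form of
the repeated-observations correlation.

## Distribution stage

Reversal-timing distributions differ in location and spread across
observers, so each observer's timings are normalized before pooling.
"Normalized by the mean of all the trials in both conditions combined"
is ambiguous between centering and standardizing; the printed group
medians (≈ −0.68 to 1.00 around 0) are consistent with a dimensionless
scale, so the default is a per-observer z-score over the combined pool
(population SD), with mean-centering available via `method = "center"`.
Histograms use 0.25-wide bins anchored at 0.

Whether the pooled unpredictable distribution is one-humped
distinguishes a weighted-averaging account (unimodal, centered within
the predictable range) from a discrete-expectation account (multimodal).
Such judgments are traditionally made by eye; `unimodality_check()`
operationalizes the question with the Hartigan dip statistic — the sup-norm
distance from the empirical cdf to the nearest unimodal cdf — against a
Monte Carlo uniform null (the least favorable unimodal case, so the test
is conservative for peaked alternatives). No dip implementation was
available in the toolchain, so the statistic is computed exactly by a
small C++ routine: for each candidate mode (an atom at a data value),
feasibility of a distance $d$ is decided from the convex-minorant band
geometry of the empirical cdf corners, and the dip is found by bisection;
the unit tests verify it against an independent linear-programming
formulation of the same minimax definition.

## Numerical and testing choices

Problem sizes were chosen to give tight Monte Carlo precision at
interactive run times: parameter recovery uses 200 simulated cohorts of
12 observers x 245 trials (Monte Carlo SE of each mean estimate ≈ 1.5%
of the largest weights); AIC-selection consistency uses 100 cohorts;
type-I-error calibration of the paired $t$ uses 10,000 null replicates
at $n = 12$; dip-test p-values use 500 uniform null draws.

One calibration fact worth recording: with the reported effect sizes as
generative truth, the $n-3$ stimulus weight has $|\beta|/\mathrm{SE}
\approx 2.6$, which corresponds to a per-dataset Wald power of ≈ 0.78 at
$\alpha = 0.05$. Its empirical significance rate over 200 simulations
matches that number to a fraction of a percent — a reminder that a
"significant in the original study" coefficient near $2\sigma$–$3\sigma$
will not replicate in every simulated repetition of the same experiment.

Determinism: every stochastic step (sequence order, timing noise, trace
noise, saccades, bootstrap) is governed by one integer seed, with
per-observer and per-block substreams derived from it, so a block's data
do not depend on how many other blocks were simulated, and identical
configurations reproduce byte-identical pipeline artifacts.

## Known limitations

* Only the right-to-left reversal is analyzed; the left-to-right
  reversal is not evaluated.
* Repeated-measures ANOVAs are out of scope; the pipeline exports tidy
  per-trial and per-observer tables an external ANOVA can consume.
* The dip test replaces a visual unimodality judgment; it is an
  operationalization of that judgment, not a re-implementation of it.
* Simulator realism is limited as described above; in particular,
  inclusion rates of simulated cohorts emerge from the timing model and
  are not calibrated to the human exclusion percentages.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- pursuit_config()
paths <- run_pipeline(cfg, out_dir = "run1", n_observers = 2, seed = 1,
                      max_blocks = 1)
readr::read_csv(paths$events)

co <- simulate_cohort(12, "unpredictable", sim_model(), seed = 1)
co$reversal_ms <- co$true_reversal_ms
grid <- model_grid_and_select(co)
glance(grid)
tidy(grid$models[[grid$selected]])
autoplot(grid)
```
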