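---
title: "Timing-only inference for broadcast communication: models and methods"
author: "chronoclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timing-only inference for broadcast communication: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronoclass)
```

`chronoclass` infers the nature of a broadcast-communication account —
one person, a managed corporate presence, or an automated system — from
nothing but the timestamps of its posts. This vignette is the package's
own account of the statistics it implements: the models, their
assumptions, the tunable parameters, and the numerical choices made where
the design was genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## Event streams and timing features

The unit of data is an *event stream*: one account's time-ordered posting
timestamps (UTC epoch seconds), a fixed per-account UTC offset in
minutes, and an optional class label. Localisation is a single constant
offset — no daylight-saving database — because an account advertises one
timezone; accounts without a declared offset cannot be localised and are
discarded by `filter_accounts()` before any clock-based analysis. Streams
are capped at the 800 most recent events by default, mirroring a typical
per-account harvest limit; the cap is configurable.

Two features drive everything downstream:

* the **inter-event delay**, the seconds elapsed between consecutive
  posts by the same account. Gaps of zero seconds (same-second posts,
  or clock skew) are floored to 1 s rather than dropped, which keeps
  series lengths predictable and log-scale binning well defined; and
* the **local posting hour** (0–23). Each delay additionally carries the
  local hour of the event *preceding* it, which is the conditioning
  variable of the hour-resolved predictor and the second coordinate of
  the joint classifier features.

Weekdays follow the ISO convention (Monday = 1). Reposts are ordinary
events: the timing signal does not distinguish authored from relayed
content.

## Empirical densities

Delay densities are histograms on 100 logarithmically spaced bins
spanning decades $10^0$–$10^7$ s (1 s to roughly 116 days) — wide enough
that no realistic account gap falls outside, and delays beyond the range
are clamped into the extreme bins rather than silently lost. The raw
histogram always integrates to exactly one; a documented *floor*
($10^{-12}$ per second for delay densities, $10^{-6}$ per hourly bin
after renormalisation) replaces empty bins only at evaluation time.
The floor is what makes the classifier's log scores finite for feature
values never seen in training — the concrete resolution of the otherwise
undefined $\log 0$.

Densities are evaluated by a monotone shape-preserving piecewise-cubic
spline (Fritsch–Carlson) through the (bin centre, density) nodes, clamped
below at the floor; queries outside the binned support return the floor.
Shape preservation matters: on sparse histograms an unconstrained cubic
spline can dip negative between nodes, which a probability density must
not do. Joint delay × hour densities come in two forms matching the two
classifier variants: the product of the marginals (independence assumed)
and a full 100 × 24 two-dimensional histogram, whose floor is the product
of the marginal floors so that scores remain comparable across modes.

## Power-law tails

The tail of the delay distribution is modelled as a continuous power law
above a lower cutoff: $P(x) \propto x^{-\alpha}$ for $x \ge x_{\min}$.
The exponent is the continuous-data maximum-likelihood estimate

$$\hat\alpha = 1 + n_{\text{tail}} \Big[ \sum_{x_i \ge x_{\min}}
\ln \frac{x_i}{x_{\min}} \Big]^{-1},$$

and $x_{\min}$ is selected by minimising the Kolmogorov–Smirnov distance
between the tail's empirical CDF and the fitted power-law CDF. A
continuous (not discrete) likelihood is used although delays have second
resolution: the data span seven decades and discreteness is negligible
above any plausible cutoff. Candidate cutoffs are the unique sample
values, thinned to at most 200 log-spaced points and restricted so at
least 50 tail samples remain; ties break to the smallest candidate
(largest tail). Goodness of fit is a parametric bootstrap: synthetic
datasets of the original size are drawn from the fitted semi-parametric
model (resampled empirical head below $x_{\min}$, fitted power law
above), each refit including cutoff selection, and the p-value is the
fraction whose KS distance reaches the observed one. The default of 100
bootstrap replicates gives a p-value resolution of 0.01 at desk scale;
publication-grade runs can raise it. The closed-form estimator is
cross-checked in the test suite against a brute-force numerical maximiser
of the tail log-likelihood, and the inverse-transform sampler
($x = x_{\min}(1-u)^{-1/(\alpha-1)}$) doubles as the bootstrap engine and
the test oracle.

## The naive-Bayes classifier

Classification is the MAP rule over empirical class densities. With
classes $c$ and per-event feature values $v_j$, an account's score is

$$S_c = \sum_j \log f_c(v_j) + \log \pi_c,$$

with uniform priors $\pi_c$ by default (balanced designs), so MAP reduces
to maximum likelihood; priors are configurable. Four feature modes are
supported: delay marginal (ITD), hour marginal (TT), their product under
independence (JI) and the full 2-D histogram (JNI). Training pools all
events of all training accounts of a class — class densities, not
per-account ones. Ties break deterministically to the first class in
model order. The JNI grid (100 × 24) deliberately subsamples the joint
space; its weakness relative to JI on small training sets is a real
property of the 2-D histogram, not an implementation accident.

Evaluation offers leave-one-out cross-validation, repeated stratified
train/test splits (each class split independently, so class balance is
preserved at every training fraction), and a chance baseline obtained by
permuting account labels before training. One caveat worth knowing:
label-shuffled LOOCV carries a mild anti-learning bias, because the
held-out account's own events are missing from the pool of the class that
bears its (shuffled) label; with balanced classes of the sizes used here
the effect stays a few points below $1/K$ and inside the binomial chance
band asserted by the tests.

Pearson and Kendall correlation tests between the delay and the
preceding-hour of pooled class pairs quantify how defensible the JI
independence assumption is; on clock-independent synthetic generators
both correlations sit near zero.

## Predicting the next delay

The class model for prediction is simply the empirical CDF of the pooled
class delays — the probability that the next event has arrived within
$t$ seconds of the previous one. Each observed delay $\tau$ of a test
account defines a step function ($0$ before $\tau$, $1$ from $\tau$ on),
and the model is scored per event by the coefficient of determination
$R^2 = 1 - SS_{\text{res}} / SS_{\text{tot}}$ on an evaluation grid, with
$SS_{\text{tot}}$ about the mean of the step values. $R^2$ is left
unclamped: negative values mean the CDF predicts that event worse than a
constant would.

The evaluation grid deserves a paragraph, because the obvious choice is
wrong. Evaluating on the CDF's own support points concentrates the grid
where the model has mass, and then delays in the extreme quantiles of the
class distribution produce arbitrarily negative $R^2$ (a delay at
empirical quantile $q$ scores roughly
$1 - [q^3 + (1-q)^3]/[3q(1-q)]$, which diverges as $q \to 0$ or $1$).
The unclamped *mean* over events is then dominated by a handful of
outliers, and comparisons between competing models become noise. The
report-level default is therefore a fixed, model-independent grid of 201
linearly spaced points over 0–$10^6$ s — the range of the uniform null
model — on which own-class means are stable and positive, and the null
model is unambiguously negative. `r2_against_step()` itself still
defaults to the CDF's support, so the op can be used with any explicit
grid, including the 5-point oracle grids in the tests.

The hour-conditioned variant fits 24 CDFs, one per preceding local hour,
with hours holding fewer than 2 delays falling back to the unconditional
CDF. On clock-independent data it reproduces the single-distribution
model to within a few thousandths of mean $R^2$ — conditioning on the
hour buys little unless delays genuinely depend on it. The null model is
the empirical CDF of seeded draws from Uniform(1, $10^6$) seconds.

## Descriptive statistics

* **Periodogram.** Event counts in fixed-width bins (3600 s default),
  mean-removed, no taper or detrending — a plain periodogram. Frequencies
  are reported in Hz and power per Hz (plus dB/Hz for display); the
  one-sided spectrum integrates to the series' biased variance, which the
  suite asserts via Parseval's identity.
* **Circular statistics.** Posting hours map to angles
  ($\theta = 2\pi h/24$); the mean direction and resultant length
  $\bar R$ give the mean posting hour, and the von Mises concentration
  $\kappa$ is recovered from $\bar R$ by the standard three-regime
  inversion. Dispersion is reported in hours as $1/\sqrt{\kappa}$, the
  large-$\kappa$ SD-equivalent of a wrapped normal; the circular standard
  deviation $\sqrt{-2\ln\bar R}$ is available by flag since either
  convention is defensible. Both are monotone decreasing in $\kappa$.
* **Signal-dependent noise.** Per-account delay mean and SD with a
  least-squares line through the scatter (log–log by flag): heavy-tailed,
  bursty streams put the SD roughly proportional to the mean.
* **Activity matrices.** Per-account event counts by ISO weekday or local
  hour, rows sorted by ascending total, optionally trimmed to the most
  active accounts — the tabular form of tile-style activity heatmaps.
  Weekday structure is descriptive output only and never enters the
  classifier's features.

## The synthetic cohort generator

The generator is first-class, tested code: it is the package's universal
fixture and defines the conditions under which every end-to-end claim is
asserted. Each class is a renewal process whose gaps come from a
two-component mixture — with probability `burst_fraction` a short
log-uniform "burst" gap, otherwise a power-law gap with the class's
`tail_alpha` and `tail_xmin` — thinned by a diurnal × weekday acceptance
profile evaluated at the candidate's local time. Rejection *extends the
current gap* (events are suppressed, never displaced), so heavy tails and
diurnal structure coexist in one process. Bots bypass the mixture:
`constant_rate` draws exponential gaps with no thinning, `spike_hours`
posts near the middle of each scheduled hour with ±10 min uniform jitter.
All randomness flows from one master seed through per-account sub-seeds,
so cohorts are reproducible as a whole and account by account; offsets
are drawn per account from a small pool of plausible timezones.

Default class parameters: personal — $\alpha = 2.4$, $x_{\min} = 300$ s,
45 % bursts of 2–250 s, evening-peaked profile with its maximum at 21 h;
managed — $\alpha = 1.9$, $x_{\min} = 600$ s, 35 % bursts, work-hours
profile peaking at 9–18 h with a dip at 12 h and weekends damped to 0.6;
bot — constant rate with a 600 s mean gap. The diurnal *shapes* follow
the behavioural phenomenology (evening-loaded personal activity, office
hours with a lunch dip for managed accounts), but they are compressed
affinely into acceptance weights no smaller than about 0.3–0.5: strong
thinning merges many candidate gaps into each quiet-hour delay, and with
night-time acceptance near 0.05 the merged gaps visibly bend the marginal
tail (the apparent exponent drops by ~0.3). With the compressed profiles
the fitted exponent recovers the specified one to within ±0.15 in the
large majority of seeds, which is the tolerance the recovery tests
assert.

What the generator does *not* emulate: content, reply structure,
follower dynamics, account lifecycle drift, daylight-saving shifts, or
heterogeneity of per-account parameters within a class (all personal
accounts share one spec, differing only in seed and timezone). Passing
tests on these cohorts therefore demonstrate that the inference machinery
recovers the structure it targets when that structure is present — not
that real platform data are this clean: real classes overlap more, and
real classification accuracy will sit well below the near-perfect
separation seen on the synthetic defaults.

## Numerical choices and degenerate inputs

* Zero/negative gaps floor to 1 s; delays are validated positive
  downstream.
* Density floors: $10^{-12}$ s$^{-1}$ (delay), $10^{-6}$ (hour),
  $10^{-18}$ (2-D grid).
* Cutoff selection requires ≥ 50 tail samples and breaks KS ties to the
  smaller cutoff; the bootstrap warns below 20 replicates and defaults to
  100.
* Classifier ties resolve to the first class in model order; scores are
  finite by construction.
* $R^2$ is undefined when every grid point lies on one side of the step
  (the error tells the caller to widen the grid); account-level reports
  drop such events and count them separately.
* Perfectly balanced circular data (resultant length 0) has no mean
  direction and errors rather than fabricating one.
* Test-suite and acceptance-script problem sizes (cohorts of 20
  accounts/class × 200 events, GOF calibration at $n = 2000$ with 100
  bootstrap replicates, estimator recovery at $n = 10^5$) are the
  package's chosen desk scale: large enough that the asserted margins are
  stable across seeds, small enough to iterate on.

## Command-line surface

`run_cli()` (wrapped by `exec/chronoclass`) exposes `simulate`,
`describe`, `fit-tail`, `classify`, `evaluate` and `predict-eval` over
JSON-lines cohorts, writing JSON reports. Invalid usage exits 2, runtime
failure 1. Every stochastic subcommand refuses to run without an explicit
`--seed`, and identical seeds give byte-identical artifacts — the same
discipline `scripts/acceptance.R` follows for the package's headline
numbers.
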