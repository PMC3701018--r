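# chronoclass

Timing-only inference for broadcast-communication event streams: who — or
what — is behind an account, judged purely by *when* it posts.

Personal social-media accounts, corporate (PR-managed) accounts and
automated bots leave very different fingerprints in the timing of their
posts, even when the content is ignored entirely. Human posting is bursty:
the delay between consecutive posts is heavy-tailed, with a power-law tail
`P(x) ~ x^(-alpha)` above a lower cutoff `x_min`, and activity follows a
daily routine (evenings for personal accounts, office hours with a lunch
dip for managed ones). Bots either tick along at a constant rate or fire
at programmed hours. `chronoclass` turns those regularities into three
tools:

1. **Tail characterisation.** Continuous maximum-likelihood fitting of the
   delay tail, `alpha_hat = 1 + n / sum(log(x_i / x_min))`, with `x_min`
   chosen by minimising the Kolmogorov–Smirnov distance between the tail
   and the fitted law, plus a semi-parametric bootstrap goodness-of-fit
   p-value and two-sample KS comparisons between classes.
2. **Account classification.** A non-parametric naive-Bayes MAP classifier
   over empirical timing densities. An account's score for class `c` is
   `S_c = sum_j log f_c(v_j)`, the summed log density of its per-event
   feature values (inter-event delay, local posting hour, or their joint,
   with or without an independence assumption); the account is assigned to
   the highest-scoring class. Leave-one-out cross-validation, repeated
   stratified train/test splits and label-shuffled chance baselines are
   built in.
3. **Next-event prediction.** The empirical CDF of a class's delays is
   used as a predictive distribution for the next delay of an unseen
   account of that class; each observed delay `tau` defines a step
   function (0 before `tau`, 1 after) and the model is scored by
   `R^2 = 1 - SS_res / SS_tot` against it, with a Uniform(1, 10^6)-seconds
   null model for calibration. A 24-distribution variant conditions on
   the hour preceding each delay.

Descriptive companions (periodogram spectra of activity, von Mises
circular statistics of posting hour, per-account SD-vs-mean delay scaling,
weekday/hour activity matrices) and a seeded synthetic cohort generator —
a thinned renewal process with class-distinct tails and diurnal profiles —
round out the package, so every stage can be exercised end to end without
any external data.

## Worked example

```r
library(chronoclass)

# a labelled synthetic cohort: 10 accounts per class, 200 events each
cohort <- simulate_cohort(n_accounts_per_class = 10, n_events = 200, seed = 42)
cohort
#> <event_cohort> 30 accounts (bot: 10, managed: 10, personal: 10)

# heavy-tail fit of the personal accounts' pooled inter-event delays
personal <- cohort[1:10]
fit <- fit_power_law(unlist(lapply(personal, function(s) compute_delays(s)$delays)))
fit
#> <power_law_fit> alpha = 2.411, xmin = 1251, KS = 0.0287, n_tail = 292

# leave-one-out classification from the joint delay x hour densities
loocv(cohort, mode = "JI")
#> <evaluation_report> mode JI, accuracy 1.000
#>           predicted
#> true       personal managed bot
#>   personal       10       0   0
#>   managed         0      10   0
#>   bot             0       0  10

# circular summary of one account's posting hours
vm <- fit_von_mises(clock_features(cohort[["personal_001"]])$local_hour)
sprintf("mean posting hour %.1f h, circular dispersion %.1f h",
        vm$mean_hour, vm$dispersion)
#> "mean posting hour 17.8 h, circular dispersion 4.1 h"
```

The tail exponent lands near the generator's personal-class value of 2.4;
the three classes separate cleanly because their delay tails and diurnal
profiles genuinely differ; and the evening-weighted personal profile pulls
the circular mean hour into the late afternoon with a few hours of spread.

A command-line surface wraps the same functions
(`exec/chronoclass simulate | describe | fit-tail | classify | evaluate |
predict-eval`); every stochastic subcommand requires an explicit `--seed`
and writes JSON reports.

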