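Package: chronoclass
Title: Timing-Only Analysis, Classification and Prediction for Broadcast
    Communication Event Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers who (or what) is behind a broadcast-communication
    account from nothing but the timing of its posts.  Provides
    empirical-density naive-Bayes classification of account type
    (personal, managed, bot) from inter-event delays and local posting
    hours, maximum-likelihood power-law fitting of heavy delay tails
    with Kolmogorov-Smirnov lower-cutoff selection and parametric
    bootstrap goodness-of-fit, renewal-style prediction of the next
    event's delay distribution scored by the coefficient of
    determination against per-event step functions, circular (von
    Mises) and spectral summaries of diurnal activity, and a seeded
    simulator of labelled account cohorts with class-distinct tails and
    diurnal profiles so every stage can be exercised without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
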