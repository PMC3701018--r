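# Shared fixture builders: everything is generated in code at test time.

# Stream from explicit epoch-second times.
make_stream <- function(times, offset = NA_integer_, label = "unlabelled",
                        id = "acct") {
  event_stream(id, times, utc_offset_min = offset, label = label)
}

# Small well-separated labelled cohort for classifier tests.
small_cohort <- function(n_per_class = 8L, n_events = 120L, seed = 301L) {
  simulate_cohort(n_accounts_per_class = n_per_class, n_events = n_events,
                  seed = seed)
}

subset_cohort <- function(cohort, classes) {
  labs <- vapply(cohort, `[[`, character(1), "label")
  event_cohort(unclass(cohort)[labs %in% classes])
}

# Von Mises sampler (Best & Fisher rejection scheme), in radians.
rvonmises <- function(n, mu, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
    }
  }
  out
}

# Hour-of-day draws around a mean hour with a given concentration.
rvonmises_hours <- function(n, mean_hour, kappa) {
  rvonmises(n, 2 * pi * mean_hour / 24, kappa) * 24 / (2 * pi)
}

# Leave-one-account-out per-event R^2 for one class of a cohort.
class_r2 <- function(cohort, label, model_kind = "single",
                     null_model = NULL) {
  labs <- vapply(cohort, `[[`, character(1), "label")
  series <- lapply(unclass(cohort)[labs == label], compute_delays)
  unlist(lapply(seq_along(series), function(i) {
    pool <- do.call(rbind, lapply(series[-i], function(d)
      cbind(d$delays, d$preceding_hour)))
    model <- if (!is.null(null_model)) {
      null_model
    } else if (model_kind == "hourly") {
      build_hourly_model(pool[, 1L], pool[, 2L])
    } else {
      build_single_model(pool[, 1L])
    }
    evaluate_account(model, series[[i]]$delays,
                     series[[i]]$preceding_hour)$r2
  }), use.names = FALSE)
}
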