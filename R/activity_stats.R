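# Descriptive timing analyses: periodogram PSD of binned activity,
# signal-dependent-noise scaling of per-account delays, von Mises circular
# statistics of posting hour, and weekly/hourly activity matrices.

#' Binned event-count time series
#'
#' @param stream An [event_stream()].
#' @param bin_width_s Bin width in seconds (default 3600).
#' @return List with `counts` (integer per bin) and `bin_width_s`.  Bins
#'   span from the first to the last event; the total count equals the
#'   number of events.
#' @export
event_rate_series <- function(stream, bin_width_s = 3600) {
  stopifnot(inherits(stream, "event_stream"))
  if (!is.numeric(bin_width_s) || bin_width_s <= 0)
    stop_chrono("bin_width_s must be positive", "chronoclass_bad_bins")
  t <- stream$t_utc
  if (!length(t))
    stop_chrono("empty stream", "chronoclass_empty_series")
  idx <- floor((t - t[1L]) / bin_width_s)
  counts <- tabulate(idx + 1L, nbins = max(idx) + 1L)
  list(counts = counts, bin_width_s = bin_width_s)
}

#' Periodogram power spectral density of an activity series
#'
#' Plain mean-removed periodogram of the binned event counts (no taper,
#' no detrending).  Frequencies are reported in Hz, derived from the bin
#' width; power is per Hz, with a dB/Hz column for log-scale display.
#' One-sided convention: interior frequencies carry the power of both
#' spectral halves, so `sum(psd) * df` equals the series' (biased)
#' variance.
#'
#' @param counts Integer event counts per bin (length >= 4), or the list
#'   returned by [event_rate_series()].
#' @param bin_width_s Bin width in seconds (ignored when `counts` carries
#'   its own).
#' @return A `periodogram_result` with `frequency` (Hz, ascending), `psd`
#'   (linear, per Hz) and `psd_db` (dB/Hz; `-Inf` where power is zero).
#' @export
activity_periodogram <- function(counts, bin_width_s = 3600) {
  if (is.list(counts)) {
    bin_width_s <- counts$bin_width_s
    counts <- counts$counts
  }
  n <- length(counts)
  if (n < 4L)
    stop_chrono("need >= 4 bins for a periodogram", "chronoclass_bad_bins")
  x <- counts - mean(counts)
  spec <- Mod(stats::fft(x))^2 / n           # raw two-sided, per sample
  half <- seq_len(floor(n / 2))              # k = 1 .. floor(n/2)
  scale <- rep(2, length(half))
  if (n %% 2 == 0) scale[length(half)] <- 1  # Nyquist bin is unpaired
  psd <- scale * spec[half + 1L] * bin_width_s
  freq <- half / (n * bin_width_s)
  structure(list(frequency = freq, psd = psd,
                 psd_db = ifelse(psd > 0, 10 * log10(psd), -Inf),
                 bin_width_s = bin_width_s, n_bins = n),
            class = "periodogram_result")
}

# Resultant-length inversion for the von Mises concentration parameter
# (standard small/large-Rbar approximation regimes).
kappa_from_rbar <- function(rbar) {
  if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
}

#' Von Mises summary of posting hours
#'
#' Maps hours to angles (`theta = 2 * pi * hour / 24`), computes the mean
#' direction and resultant length, inverts the resultant length into the
#' von Mises concentration `kappa`, and converts `kappa` into a circular
#' dispersion in hour units - an SD-equivalent spread around the mean
#' posting hour.  Two conversions are available: `1/sqrt(kappa)` (the
#' large-kappa SD of a wrapped normal, the default) and the circular
#' standard deviation `sqrt(-2 log(Rbar))`.
#'
#' @param hours Local hours, 0-23 (fractions allowed), length >= 2.
#' @param dispersion `"inv_sqrt_kappa"` or `"circ_sd"`.
#' @return A `circular_summary`: `mean_hour` in [0, 24), `kappa`,
#'   `resultant_length`, `dispersion` (hours), `n`.
#' @export
fit_von_mises <- function(hours, dispersion = c("inv_sqrt_kappa",
                                                "circ_sd")) {
  dispersion <- match.arg(dispersion)
  hours <- as.numeric(hours)
  if (length(hours) < 2L)
    stop_chrono("need >= 2 events for circular statistics",
                "chronoclass_empty_series")
  theta <- 2 * pi * hours / 24
  C <- mean(cos(theta)); S <- mean(sin(theta))
  rbar <- sqrt(C^2 + S^2)
  if (rbar < 1e-12)
    stop_chrono("resultant length ~ 0: mean direction undefined",
                "chronoclass_degenerate")
  mean_hour <- (atan2(S, C) %% (2 * pi)) * 24 / (2 * pi)
  kappa <- kappa_from_rbar(min(rbar, 1 - 1e-12))
  disp_rad <- switch(dispersion,
                     inv_sqrt_kappa = 1 / sqrt(kappa),
                     circ_sd = sqrt(-2 * log(rbar)))
  structure(list(mean_hour = mean_hour, kappa = kappa,
                 resultant_length = rbar,
                 dispersion = disp_rad * 24 / (2 * pi),
                 dispersion_type = dispersion, n = length(hours)),
            class = "circular_summary")
}

#' Signal-dependent noise: per-account delay SD versus mean
#'
#' Computes the mean and standard deviation of each account's delays and
#' fits a least-squares line through the (mean, SD) scatter - optionally
#' on log-log axes.  A slope near one with high correlation is the
#' signature of signal-dependent noise (variability proportional to the
#' mean).
#'
#' @param cohort An [event_cohort()]; accounts with < 2 delays are skipped
#'   with a warning.
#' @param log_scale Fit on log10 axes instead of linear.
#' @return A `scaling_fit`: per-account data frame `points`
#'   (`account_id`, `mean_delay`, `sd_delay`), `slope`, `intercept`, `r`.
#' @export
mean_sd_scaling <- function(cohort, log_scale = FALSE) {
  stopifnot(inherits(cohort, "event_cohort"))
  rows <- lapply(cohort, function(s) {
    if (n_events(s) < 3L) return(NULL)  # < 2 delays
    d <- compute_delays(s)$delays
    data.frame(account_id = s$account_id, mean_delay = mean(d),
               sd_delay = stats::sd(d), stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped)
    warning(sprintf("skipped %d account(s) with < 2 delays", skipped))
  pts <- do.call(rbind, rows)
  if (is.null(pts) || nrow(pts) < 2L)
    stop_chrono("need >= 2 accounts with >= 2 delays for a scaling fit",
                "chronoclass_degenerate")
  x <- pts$mean_delay; y <- pts$sd_delay
  if (log_scale) { x <- log10(x); y <- log10(y) }
  fit <- stats::lm.fit(cbind(1, x), y)
  structure(list(points = pts, slope = unname(fit$coefficients[2L]),
                 intercept = unname(fit$coefficients[1L]),
                 r = stats::cor(x, y), log_scale = log_scale),
            class = "scaling_fit")
}

#' Per-account weekday or hourly activity matrix
#'
#' Counts each account's events per ISO weekday (Monday = 1) or per local
#' hour, sorts accounts by ascending total activity and keeps the
#' `top_n` most active - the matrix behind tile-style activity heatmaps.
#'
#' @param cohort An [event_cohort()] of localised accounts.
#' @param axis `"weekday"` or `"hour"`.
#' @param top_n Keep this many most-active accounts (default: all).
#' @return An `activity_matrix`: integer matrix (accounts x 7 or 24) with
#'   account ids as row names, rows ordered by ascending total.
#' @export
activity_matrix <- function(cohort, axis = c("weekday", "hour"),
                            top_n = Inf) {
  axis <- match.arg(axis)
  stopifnot(inherits(cohort, "event_cohort"))
  ncol <- if (axis == "weekday") 7L else 24L
  m <- t(vapply(cohort, function(s) {
    cf <- clock_features(s)
    v <- if (axis == "weekday") cf$weekday else cf$local_hour + 1L
    tabulate(v, nbins = ncol)
  }, integer(ncol)))
  rownames(m) <- names(cohort)
  colnames(m) <- if (axis == "weekday") {
    c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  } else {
    sprintf("h%02d", 0:23)
  }
  totals <- rowSums(m)
  keep <- order(totals, decreasing = TRUE)[seq_len(min(top_n, nrow(m)))]
  m <- m[keep, , drop = FALSE]
  m <- m[order(rowSums(m)), , drop = FALSE]
  structure(m, axis = axis, class = c("activity_matrix", class(m)))
}
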