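# Empirical feature densities: log-binned delay PDF, hour-of-day mass,
# their joint (product form or full 2-D histogram) and empirical CDFs.
# These densities back both the naive-Bayes classifier and the figures-style
# descriptive output, so normalisation and flooring are handled carefully:
# the raw histogram always integrates to one, and a small documented floor
# replaces empty bins only where densities are *evaluated*, keeping log
# scores finite for feature values never seen in training.

#' Logarithmic bin edges for delay histograms
#'
#' @param decades Length-2 integer-ish vector: powers of ten spanned
#'   (default `c(0, 7)`, i.e. 1 s to ~116 days).
#' @param n_bins Number of bins (default 100).
#' @return Numeric vector of `n_bins + 1` strictly increasing edges.
#' @export
log_bin_edges <- function(decades = c(0, 7), n_bins = 100L) {
  stopifnot(length(decades) == 2L, decades[1] < decades[2], n_bins >= 1L)
  10^seq(decades[1], decades[2], length.out = n_bins + 1L)
}

#' Fit the log-binned inter-event delay density
#'
#' Histogram of positive delays on logarithmically spaced bins, normalised
#' to integrate to one (probability per second).  Delays outside the binned
#' range are clamped into the extreme bins so no mass is silently lost.
#'
#' @param delays Positive delays, seconds.
#' @param decades,n_bins Passed to [log_bin_edges()].
#' @param floor Density floor substituted for empty bins at evaluation
#'   time (default `1e-12` per second).
#' @return A `log_binned_density` with fields `bin_edges`, `centres`
#'   (geometric bin centres), `density` (floored), `density_raw`,
#'   `floor`, `n_samples`.
#' @export
fit_delay_density <- function(delays, decades = c(0, 7), n_bins = 100L,
                              floor = 1e-12) {
  delays <- as.numeric(delays)
  if (!length(delays))
    stop_chrono("no delays to bin", "chronoclass_empty_series")
  if (any(!is.finite(delays) | delays <= 0))
    stop_chrono("delays must be positive and finite (floor gaps upstream)",
                "chronoclass_bad_delay")
  edges <- log_bin_edges(decades, n_bins)
  n_bins <- length(edges) - 1L
  x <- pmin(pmax(delays, edges[1L]), edges[n_bins + 1L])
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  widths <- diff(edges)
  raw <- counts / (length(delays) * widths)
  structure(
    list(bin_edges = edges,
         centres = sqrt(edges[-1L] * edges[-(n_bins + 1L)]),
         density = pmax(raw, floor),
         density_raw = raw,
         floor = floor,
         n_samples = length(delays)),
    class = "log_binned_density"
  )
}

#' Fit the hour-of-day mass function
#'
#' Relative frequency of events per local hourly bin (0 = midnight ... 23),
#' with an additive floor on empty hours followed by renormalisation, so
#' that log scores of unseen hours remain finite.
#'
#' @param hours Integer hours in 0-23.
#' @param floor Additive mass floor for empty hours (default `1e-6`).
#' @return An `hour_density` with `mass` (sums to 1), `mass_raw`,
#'   `floor`, `n_samples`.
#' @export
fit_hour_density <- function(hours, floor = 1e-6) {
  hours <- as.integer(hours)
  if (!length(hours))
    stop_chrono("no hours to bin", "chronoclass_empty_series")
  if (anyNA(hours) || any(hours < 0L | hours > 23L))
    stop_chrono("hours must lie in 0..23", "chronoclass_bad_hour")
  raw <- tabulate(hours + 1L, nbins = 24L) / length(hours)
  mass <- raw
  mass[mass == 0] <- floor
  mass <- mass / sum(mass)
  structure(list(mass = mass, mass_raw = raw, floor = floor,
                 n_samples = length(hours)),
            class = "hour_density")
}

#' Joint delay-hour density
#'
#' Either the product of the two fitted marginals (`independent`, the JI
#' feature model) or a full 100 x 24 two-dimensional histogram over paired
#' `(delay, preceding hour)` samples (`full2d`, the JNI feature model).
#' The 2-D grid holds probability per second per hour-bin; its floor is the
#' product of the marginal floors so scores are comparable across modes.
#'
#' @param delay_density A [fit_delay_density()] result.
#' @param hour_density A [fit_hour_density()] result.
#' @param mode `"independent"` or `"full2d"`.
#' @param delays,hours Paired samples, required for `full2d`.
#' @return A `joint_density`.
#' @export
fit_joint <- function(delay_density, hour_density,
                      mode = c("independent", "full2d"),
                      delays = NULL, hours = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(delay_density, "log_binned_density"),
            inherits(hour_density, "hour_density"))
  out <- list(mode = mode, delay_density = delay_density,
              hour_density = hour_density)
  if (mode == "full2d") {
    if (is.null(delays) || is.null(hours) || length(delays) != length(hours))
      stop_chrono("full2d mode needs paired delays and hours",
                  "chronoclass_bad_pairs")
    ok <- !is.na(hours)
    delays <- delays[ok]; hours <- as.integer(hours[ok])
    edges <- delay_density$bin_edges
    nb <- length(edges) - 1L
    di <- findInterval(pmin(pmax(delays, edges[1L]), edges[nb + 1L]),
                       edges, rightmost.closed = TRUE)
    counts <- matrix(tabulate((hours) * nb + di, nbins = nb * 24L),
                     nrow = nb, ncol = 24L)
    widths <- diff(edges)
    raw <- counts / (length(delays) * widths)  # per second per hour-bin
    out$floor <- delay_density$floor * hour_density$floor
    out$grid_raw <- raw
    out$grid <- pmax(raw, out$floor)
    out$n_samples <- length(delays)
  }
  structure(out, class = "joint_density")
}

monotone_spline <- function(x, y) {
  stats::splinefun(x, y, method = "monoH.FC")
}

#' Evaluate a fitted density
#'
#' Densities are evaluated by a monotone shape-preserving piecewise-cubic
#' spline through the (bin centre, density) nodes, clamped below at the
#' floor; queries outside the binned support return the floor.  Shape
#' preservation matters on sparse histograms, where an unconstrained cubic
#' spline can dip negative between bins.
#'
#' @param density A `log_binned_density`, `hour_density` or `joint_density`.
#' @param ... Query values: `q` (delay seconds) for delay densities,
#'   `hour` for hour densities, both for joints.
#' @return Non-negative density values, never below the floor, never `NaN`.
#' @export
density_at <- function(density, ...) UseMethod("density_at")

#' @rdname density_at
#' @param q Delay queries, seconds.
#' @export
density_at.log_binned_density <- function(density, q, ...) {
  f <- attr(density, "spline")
  if (is.null(f)) f <- monotone_spline(log10(density$centres), density$density)
  q <- as.numeric(q)
  out <- rep(density$floor, length(q))
  inside <- is.finite(q) & q >= density$centres[1L] &
    q <= density$centres[length(density$centres)]
  if (any(inside)) out[inside] <- pmax(density$floor, f(log10(q[inside])))
  out
}

#' @rdname density_at
#' @param hour Hour queries, integers 0-23.
#' @export
density_at.hour_density <- function(density, hour, ...) {
  hour <- as.integer(hour)
  out <- rep(density$floor, length(hour))
  ok <- !is.na(hour) & hour >= 0L & hour <= 23L
  out[ok] <- density$mass[hour[ok] + 1L]
  out
}

#' @rdname density_at
#' @export
density_at.joint_density <- function(density, q, hour, ...) {
  if (density$mode == "independent")
    return(density_at(density$delay_density, q) *
             density_at(density$hour_density, hour))
  hour <- as.integer(hour)
  q <- as.numeric(q)
  stopifnot(length(q) == length(hour))
  out <- rep(density$floor, length(q))
  centres <- density$delay_density$centres
  ok <- !is.na(hour) & hour >= 0L & hour <= 23L & is.finite(q) &
    q >= centres[1L] & q <= centres[length(centres)]
  if (!any(ok)) return(out)
  splines <- attr(density, "splines")
  for (h in unique(hour[ok])) {
    sel <- ok & hour == h
    f <- if (!is.null(splines)) splines[[h + 1L]] else
      monotone_spline(log10(centres), density$grid[, h + 1L])
    out[sel] <- pmax(density$floor, f(log10(q[sel])))
  }
  out
}

#' Empirical CDF / CCDF of a delay sample
#'
#' `build_cdf()` returns the right-continuous empirical distribution
#' function on the sorted unique delays; `build_ccdf()` its complement
#' `P(X > x)`, which equals 1 just below the smallest delay.
#'
#' @param delays Positive delays, seconds.
#' @return An `empirical_cdf` (or `empirical_ccdf`) with fields `support`
#'   (sorted unique values) and `value`.
#' @export
build_cdf <- function(delays) {
  delays <- as.numeric(delays)
  if (!length(delays) || any(!is.finite(delays)))
    stop_chrono("need at least one finite delay", "chronoclass_empty_series")
  tab <- table(delays)
  support <- as.numeric(names(tab))
  value <- cumsum(as.numeric(tab)) / length(delays)
  structure(list(support = support, value = value,
                 n_samples = length(delays)),
            class = "empirical_cdf")
}

#' @rdname build_cdf
#' @export
build_ccdf <- function(delays) {
  cdf <- build_cdf(delays)
  structure(list(support = cdf$support, value = 1 - cdf$value,
                 n_samples = cdf$n_samples),
            class = "empirical_ccdf")
}

#' Evaluate an empirical CDF / CCDF
#'
#' @param cdf A [build_cdf()] / [build_ccdf()] result.
#' @param q Query values.
#' @return `P(X <= q)` (or `P(X > q)`), right-continuous.
#' @export
cdf_at <- function(cdf, q) {
  idx <- findInterval(q, cdf$support)
  out <- numeric(length(q))
  out[idx > 0L] <- cdf$value[idx[idx > 0L]]
  if (inherits(cdf, "empirical_ccdf")) out[idx == 0L] <- 1
  out
}

#' Serialise / restore a density to plain JSON
#'
#' @param density A `log_binned_density` or `hour_density`.
#' @param path Output file.
#' @return `path` invisibly; `density_from_json()` returns the object.
#' @export
density_to_json <- function(density, path) {
  obj <- unclass(density)
  obj$.class <- class(density)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname density_to_json
#' @export
density_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$.class
  obj$.class <- NULL
  structure(obj, class = cls)
}
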