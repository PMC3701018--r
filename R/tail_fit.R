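# Power-law characterisation of heavy delay tails: continuous MLE for the
# exponent, KS-minimising lower-cutoff selection, parametric-bootstrap
# goodness of fit, and two-sample KS comparison between delay samples.
# The estimator follows the standard continuous-data formulation
# alpha_hat = 1 + n / sum(log(x_i / xmin)) over the tail x_i >= xmin,
# with xmin chosen to minimise the Kolmogorov-Smirnov distance between the
# tail's empirical CDF and the fitted power-law CDF.

#' Continuous power-law exponent by maximum likelihood
#'
#' @param samples Positive sample values.
#' @param xmin Lower cutoff; only `samples >= xmin` enter the fit.
#' @return The MLE `alpha_hat > 1`.
#' @export
mle_alpha <- function(samples, xmin) {
  stopifnot(is.numeric(samples), is.numeric(xmin), xmin > 0)
  tail <- samples[samples >= xmin]
  if (length(tail) < 2L)
    stop_chrono("need >= 2 tail samples at or above xmin",
                "chronoclass_empty_tail")
  s <- sum(log(tail / xmin))
  if (s <= 0)
    stop_chrono("all tail samples equal xmin: exponent diverges",
                "chronoclass_degenerate_tail")
  1 + length(tail) / s
}

# KS distance between the tail empirical CDF and the fitted power-law CDF,
# evaluated at the (sorted) tail points with both one-sided gaps.
power_law_ks <- function(tail_sorted, xmin, alpha) {
  n <- length(tail_sorted)
  fit_cdf <- 1 - (tail_sorted / xmin)^(-(alpha - 1))
  max(abs(fit_cdf - seq_len(n) / n), abs(fit_cdf - (seq_len(n) - 1) / n))
}

#' Select the power-law lower cutoff by KS minimisation
#'
#' For each candidate cutoff the exponent is refit by MLE and the KS
#' distance between the tail empirical CDF and the fitted CDF computed;
#' the candidate with the smallest distance wins, ties going to the
#' smallest cutoff (largest tail).  The default candidate grid is the
#' unique sample values thinned to at most `max_candidates` log-spaced
#' points, restricted so at least `min_tail` samples remain above.
#'
#' @param samples Positive sample values.
#' @param candidates Optional explicit candidate cutoffs.
#' @param min_tail Minimum tail size (default 50).
#' @param max_candidates Cap on the thinned candidate grid (default 200).
#' @return List with `xmin`, `alpha`, `ks_distance`, `n_tail`.
#' @export
select_xmin <- function(samples, candidates = NULL, min_tail = 50L,
                        max_candidates = 200L) {
  x <- sort(as.numeric(samples[is.finite(samples) & samples > 0]))
  n <- length(x)
  if (is.null(candidates)) {
    if (n < min_tail)
      stop_chrono(sprintf("only %d samples; min tail size is %d", n, min_tail),
                  "chronoclass_empty_tail")
    u <- unique(x[seq_len(n - min_tail + 1L)])
    if (length(u) > max_candidates) {
      targets <- 10^seq(log10(u[1L]), log10(u[length(u)]),
                        length.out = max_candidates)
      u <- unique(u[pmax(1L, findInterval(targets, u))])
    }
    candidates <- u
  } else {
    candidates <- sort(unique(as.numeric(candidates)))
    candidates <- candidates[vapply(candidates,
                                    function(cc) sum(x >= cc) >= max(2L, min_tail * (length(candidates) > 1L)),
                                    logical(1))]
    if (!length(candidates))
      stop_chrono("no candidate cutoff leaves a large enough tail",
                  "chronoclass_empty_tail")
  }
  suffix_log <- rev(cumsum(rev(log(x))))
  best <- NULL
  for (cand in candidates) {
    i0 <- n - sum(x >= cand) + 1L
    nt <- n - i0 + 1L
    if (nt < 2L) next
    s <- suffix_log[i0] - nt * log(cand)
    if (s <= 0) next
    alpha <- 1 + nt / s
    d <- power_law_ks(x[i0:n], cand, alpha)
    if (is.null(best) || d < best$ks_distance)
      best <- list(xmin = cand, alpha = alpha, ks_distance = d, n_tail = nt)
  }
  if (is.null(best))
    stop_chrono("no valid cutoff candidate", "chronoclass_empty_tail")
  best
}

#' Fit a power law to the tail of a delay sample
#'
#' Convenience wrapper: selects `xmin` by KS minimisation (unless given),
#' fits the exponent, and optionally attaches a bootstrap p-value.
#'
#' @param samples Positive delays, seconds.
#' @param xmin Optional fixed lower cutoff; when `NULL` it is selected.
#' @param min_tail,max_candidates Passed to [select_xmin()].
#' @param n_boot Bootstrap replicates for the goodness-of-fit p-value;
#'   `0` skips the bootstrap (`p_value = NA`).
#' @param seed Optional RNG seed for the bootstrap.
#' @return A `power_law_fit`: `alpha`, `xmin`, `ks_distance`, `n_tail`,
#'   `p_value`.
#' @export
fit_power_law <- function(samples, xmin = NULL, min_tail = 50L,
                          max_candidates = 200L, n_boot = 0L, seed = NULL) {
  if (is.null(xmin)) {
    sel <- select_xmin(samples, min_tail = min_tail,
                       max_candidates = max_candidates)
  } else {
    alpha <- mle_alpha(samples, xmin)
    tail <- sort(samples[samples >= xmin])
    sel <- list(xmin = xmin, alpha = alpha,
                ks_distance = power_law_ks(tail, xmin, alpha),
                n_tail = length(tail))
  }
  fit <- structure(c(sel, list(p_value = NA_real_)), class = "power_law_fit")
  if (n_boot > 0L)
    fit$p_value <- gof_pvalue(fit, samples, n_boot = n_boot, seed = seed,
                              min_tail = min_tail,
                              max_candidates = max_candidates)
  fit
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> alpha = %.3f, xmin = %.4g, KS = %.4f, n_tail = %d%s\n",
              x$alpha, x$xmin, x$ks_distance, x$n_tail,
              if (is.na(x$p_value)) "" else sprintf(", p = %.3f", x$p_value)))
  invisible(x)
}

#' Parametric-bootstrap goodness of fit for a power-law tail
#'
#' Draws `n_boot` synthetic datasets of the original size from the fitted
#' semi-parametric model — resampled empirical head below `xmin`, fitted
#' power law above — refits each (including cutoff selection) and reports
#' the fraction whose KS distance is at least the observed one.
#'
#' @param fit A `power_law_fit` obtained from `samples`.
#' @param samples The data the fit was obtained from.
#' @param n_boot Number of bootstrap replicates (>= 20; default 100).
#' @param seed Optional RNG seed.
#' @param min_tail,max_candidates Refit settings, matching the original.
#' @return Bootstrap p-value in `[0, 1]`.
#' @export
gof_pvalue <- function(fit, samples, n_boot = 100L, seed = NULL,
                       min_tail = 50L, max_candidates = 200L) {
  stopifnot(inherits(fit, "power_law_fit"))
  if (n_boot < 20L)
    stop_chrono("n_boot < 20 gives too coarse a p-value",
                "chronoclass_bad_nboot")
  x <- samples[is.finite(samples) & samples > 0]
  n <- length(x)
  head_vals <- x[x < fit$xmin]
  p_tail <- fit$n_tail / n
  local_seed(seed, {
    ks_boot <- vapply(seq_len(n_boot), function(b) {
      m <- stats::rbinom(1L, n, p_tail)
      if (m == n || !length(head_vals)) {
        sim <- sample_power_law(n, fit$alpha, fit$xmin)
      } else {
        sim <- c(sample(head_vals, n - m, replace = TRUE),
                 sample_power_law(m, fit$alpha, fit$xmin))
      }
      ref <- tryCatch(
        select_xmin(sim, min_tail = min(min_tail, max(2L, m)),
                    max_candidates = max_candidates),
        chronoclass_error = function(e) NULL)
      if (is.null(ref)) NA_real_ else ref$ks_distance
    }, numeric(1))
    mean(ks_boot >= fit$ks_distance, na.rm = TRUE)
  })
}

#' Draw from a continuous power law by inverse transform
#'
#' `x = xmin * (1 - u)^(-1 / (alpha - 1))` with `u ~ Uniform(0, 1)`.
#'
#' @param n Number of draws.
#' @param alpha Exponent, must exceed 1.
#' @param xmin Lower cutoff, positive.
#' @param seed Optional RNG seed (caller RNG state is restored).
#' @return Numeric vector of `n` draws `>= xmin`.
#' @export
sample_power_law <- function(n, alpha, xmin, seed = NULL) {
  if (alpha <= 1)
    stop_chrono("alpha <= 1: power law not normalisable",
                "chronoclass_bad_alpha")
  stopifnot(xmin > 0, n >= 0)
  local_seed(seed, xmin * (1 - stats::runif(n))^(-1 / (alpha - 1)))
}

#' Two-sided two-sample Kolmogorov-Smirnov test
#'
#' Sup-norm distance between the two empirical CDFs with the asymptotic
#' two-sided p-value; used to compare delay distributions between account
#' classes.  Ties (second-resolution delays) are tolerated, with the usual
#' caveat that the asymptotic p is then approximate.
#'
#' @param a,b Non-empty numeric samples.
#' @return List with `D` and `p`.
#' @export
two_sample_ks <- function(a, b) {
  stopifnot(length(a) > 0L, length(b) > 0L)
  res <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(res$statistic), p = res$p.value)
}
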