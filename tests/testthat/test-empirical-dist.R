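# Log-binned delay densities, hour mass, joints and empirical CDFs.

test_that("delay histogram concentrates mass and normalises", {
  d <- fit_delay_density(rep(1000, 50))
  i <- findInterval(1000, d$bin_edges)
  w <- diff(d$bin_edges)[i]
  expect_equal(d$density_raw[i] * w, 1)
  expect_equal(sum(d$density_raw * diff(d$bin_edges)), 1)

  single <- fit_delay_density(123)
  expect_equal(sum(single$density_raw * diff(single$bin_edges)), 1)
  expect_equal(sum(single$density_raw > 0), 1L)
})

test_that("uniform draws integrate to one over their support", {
  set.seed(41)
  d <- fit_delay_density(runif(1e5, 10, 100))
  covers <- d$bin_edges[-1] > 10 & d$bin_edges[-length(d$bin_edges)] < 100
  integral <- sum((d$density_raw * diff(d$bin_edges))[covers])
  expect_equal(integral, 1, tolerance = 0.01)
})

test_that("delay density rejects non-positive input", {
  expect_error(fit_delay_density(c(10, 0)), class = "chronoclass_bad_delay")
  expect_error(fit_delay_density(numeric(0)),
               class = "chronoclass_empty_series")
})

test_that("hour mass is a floored, renormalised relative frequency", {
  h <- fit_hour_density(rep(21L, 40))
  expect_equal(sum(h$mass), 1, tolerance = 1e-9)
  expect_gt(h$mass[22], 0.999)
  expect_true(all(h$mass > 0))

  set.seed(42)
  hu <- fit_hour_density(sample(0:23, 1e4, replace = TRUE))
  expect_true(all(abs(hu$mass - 1 / 24) < 0.01))

  one <- fit_hour_density(5L)
  expect_gt(one$mass[6], 0.99)
  expect_error(fit_hour_density(24L), class = "chronoclass_bad_hour")
})

test_that("independent joint evaluates as the product of marginals", {
  set.seed(7)
  delays <- sample_power_law(500, 2.3, 10)
  hours <- sample(0:23, 500, replace = TRUE)
  jd <- fit_joint(fit_delay_density(delays), fit_hour_density(hours),
                  mode = "independent")
  q <- c(15, 120, 5000)
  hq <- c(3L, 12L, 21L)
  expect_equal(density_at(jd, q = q, hour = hq),
               density_at(jd$delay_density, q) *
                 density_at(jd$hour_density, hq))
})

test_that("full2d grid matches the outer product under independence", {
  set.seed(8)
  delays <- sample_power_law(1e5, 2.3, 10)
  hours <- sample(0:23, 1e5, replace = TRUE)
  dd <- fit_delay_density(delays)
  hd <- fit_hour_density(hours)
  jd <- fit_joint(dd, hd, mode = "full2d", delays = delays, hours = hours)
  outer_raw <- outer(dd$density_raw, hd$mass_raw)
  expect_lt(max(abs(jd$grid_raw - outer_raw)), 5e-4)
  # exact marginalisation over hours (same sample backs both fits)
  expect_equal(rowSums(jd$grid_raw), dd$density_raw)
})

test_that("full2d detects perfect coupling where the product fails", {
  hours <- rep(0:23, each = 50)
  delays <- 10^(1 + hours / 4)  # one delay bin per hour
  dd <- fit_delay_density(delays)
  hd <- fit_hour_density(hours)
  jd <- fit_joint(dd, hd, mode = "full2d", delays = delays, hours = hours)
  off_diag <- density_at(jd, q = 10^(1 + 23 / 4), hour = 0L)
  on_diag <- density_at(jd, q = 10^(1 + 23 / 4), hour = 23L)
  expect_gt(on_diag, 1e3 * off_diag)
  prod_val <- density_at(dd, 10^(1 + 23 / 4)) * density_at(hd, 0L)
  expect_gt(prod_val, 1e3 * off_diag)  # the product form misses the coupling
  expect_error(fit_joint(dd, hd, mode = "full2d"),
               class = "chronoclass_bad_pairs")
})

test_that("density interpolation is exact at nodes and floored outside", {
  d <- fit_delay_density(c(rep(100, 30), rep(1000, 30), rep(10000, 30)))
  i <- findInterval(1000, d$bin_edges)
  expect_equal(density_at(d, d$centres[i]), d$density[i])
  # between two equal-density bins the monotone spline may not overshoot
  j <- which(d$density_raw > 0)[1:2]
  mid_q <- sqrt(d$centres[j[1]] * d$centres[j[2]])
  expect_lte(density_at(d, mid_q), max(d$density[j[1]:j[2]]) + 1e-12)
  expect_equal(density_at(d, 1e9), d$floor)
  expect_equal(density_at(d, 1e-3), d$floor)
})

test_that("density evaluation never returns NaN or sub-floor values", {
  set.seed(9)
  for (rep in 1:5) {
    d <- fit_delay_density(sample_power_law(200, 2 + runif(1), 5))
    q <- 10^runif(200, -2, 9)
    v <- density_at(d, q)
    expect_true(all(is.finite(v)))
    expect_true(all(v >= d$floor))
  }
})

test_that("empirical CDF and CCDF obey their defining identities", {
  cdf <- build_cdf(c(10, 20, 30))
  expect_equal(cdf_at(cdf, 20), 2 / 3)
  expect_equal(cdf_at(cdf, 19.9), 1 / 3)
  expect_equal(cdf_at(cdf, 5), 0)
  ccdf <- build_ccdf(c(10, 20, 30))
  q <- c(5, 10, 15, 20, 25, 30, 35)
  expect_equal(cdf_at(cdf, q) + cdf_at(ccdf, q), rep(1, length(q)))
  expect_true(all(diff(cdf$value) >= 0))
  expect_equal(cdf$value[length(cdf$value)], 1)
})

test_that("empirical CDF tracks the generating distribution (DKW)", {
  set.seed(10)
  x <- rexp(1e4, rate = 1 / 100)
  cdf <- build_cdf(x)
  expect_lt(max(abs(cdf$value - (1 - exp(-cdf$support / 100)))), 0.02)
})

test_that("densities survive a JSON round trip", {
  d <- fit_delay_density(c(10, 100, 1000))
  p <- withr::local_tempfile(fileext = ".json")
  density_to_json(d, p)
  back <- density_from_json(p)
  expect_s3_class(back, "log_binned_density")
  expect_equal(back$density, d$density)
  expect_equal(density_at(back, 100), density_at(d, 100))
})
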