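# Ingestion, localisation and delay/clock featurisation.

test_that("parse_events sorts, groups and flags records", {
  df <- data.frame(
    account_id = c("a", "b", "a", "a"),
    t_utc = c("1970-01-01T00:01:40Z", "1970-01-01T00:00:05Z",
              "1970-01-01T00:00:10Z", "1970-01-01T00:00:50Z"),
    utc_offset_min = c(60L, NA, 60L, 60L),
    label = c("personal", NA, "personal", "personal"),
    stringsAsFactors = FALSE
  )
  cohort <- parse_events(df)
  expect_s3_class(cohort, "event_cohort")
  expect_length(cohort, 2L)
  expect_equal(cohort[["a"]]$t_utc, c(10, 50, 100))
  expect_equal(vapply(cohort, function(s) length(s$t_utc), integer(1)),
               c(a = 3L, b = 1L))
  expect_true(is.na(cohort[["b"]]$utc_offset_min))
  expect_identical(cohort[["a"]]$label, "personal")
})

test_that("parse_events is invariant to record order and deduplicates", {
  df <- data.frame(account_id = "a",
                   t_utc = c(100, 10, 50), utc_offset_min = 0L)
  shuffled <- df[c(2, 3, 1), ]
  expect_identical(parse_events(df)[["a"]]$t_utc,
                   parse_events(shuffled)[["a"]]$t_utc)
  dup <- rbind(df, df[1, ])
  expect_warning(cohort <- parse_events(dup), "duplicate")
  expect_length(cohort[["a"]]$t_utc, 3L)
})

test_that("malformed timestamps raise a record-level error", {
  df <- data.frame(account_id = "a",
                   t_utc = c("1970-01-01T00:00:10Z", "not-a-time"),
                   utc_offset_min = 0L)
  expect_error(parse_events(df), "record\\(s\\) 2",
               class = "chronoclass_bad_time")
})

test_that("compute_delays floors zero gaps and tags preceding hours", {
  s <- make_stream(c(0, 10, 10))
  d <- compute_delays(s)
  expect_s3_class(d, "delay_series")
  expect_equal(d$delays, c(10, 1))

  s2 <- make_stream(c(0, 3600), offset = 60L)
  d2 <- compute_delays(s2)
  expect_equal(d2$delays, 3600)
  expect_equal(d2$preceding_hour, 1L)  # local clock of the earlier event

  expect_equal(compute_delays(make_stream(c(0, 86400)))$delays, 86400)
  expect_error(compute_delays(make_stream(0)),
               class = "chronoclass_empty_series")
})

test_that("delays conserve the total span when no flooring fires", {
  t <- cumsum(c(0, sample(5:50, 20, replace = TRUE)))
  d <- compute_delays(make_stream(t))
  expect_equal(sum(d$delays), t[length(t)] - t[1])
})

test_that("clock features follow the fixed per-account offset", {
  expect_equal(clock_features(make_stream(c(0, 1), offset = -300L))$local_hour[1],
               19L)
  cf <- clock_features(make_stream(c(0, 1), offset = 0L))
  expect_equal(cf$weekday[1], 4L)  # the epoch fell on a Thursday
  expect_equal(cf$local_hour[1], 0L)
  # +840 min pushes past midnight and wraps both hour and weekday
  cf2 <- clock_features(make_stream(86000, offset = 840L))
  expect_equal(cf2$local_hour, 13L)
  expect_equal(cf2$weekday, 5L)
  expect_error(clock_features(make_stream(c(0, 1))),
               "filter_accounts", class = "chronoclass_missing_offset")
})

test_that("filter_accounts drops offset-less and short accounts", {
  cohort <- event_cohort(list(
    make_stream(c(0, 10), offset = 0L, id = "ok"),
    make_stream(c(0, 10), id = "no_tz"),
    make_stream(5, offset = 0L, id = "short")
  ))
  kept <- filter_accounts(cohort, min_events = 2L, require_offset = TRUE)
  expect_setequal(names(kept), "ok")
  expect_setequal(attr(kept, "discarded"), c("no_tz", "short"))
  ident <- filter_accounts(cohort, min_events = 0L, require_offset = FALSE)
  expect_length(ident, 3L)
})

test_that("the history cap keeps the most recent events", {
  s <- event_stream("a", 1:1000, utc_offset_min = 0L, history_cap = 800L)
  expect_length(s$t_utc, 800L)
  expect_equal(s$t_utc[1], 201)
})

test_that("write_events round-trips bit-stably in both dialects", {
  cohort <- simulate_cohort(n_accounts_per_class = 2L, n_events = 20L,
                            seed = 17L)
  for (fmt in c("jsonl", "csv")) {
    p1 <- withr::local_tempfile(fileext = paste0(".", fmt))
    p2 <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_events(cohort, p1, fmt)
    back <- parse_events(p1)
    expect_setequal(names(back), names(cohort))
    for (id in names(cohort)) {
      expect_equal(back[[id]]$t_utc, cohort[[id]]$t_utc)
      expect_equal(back[[id]]$utc_offset_min, cohort[[id]]$utc_offset_min)
      expect_identical(back[[id]]$label, cohort[[id]]$label)
    }
    write_events(back, p2, fmt)
    expect_identical(readLines(p1), readLines(p2))
  }
})
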