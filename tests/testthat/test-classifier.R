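# MAP naive-Bayes classification from empirical timing densities.

two_class_cohort <- function() {
  # class A: short delays, class B: long delays, both localised
  streams <- c(
    lapply(1:3, function(i) make_stream(cumsum(c(0, rep(60, 40))) + i,
                                        offset = 0L, label = "personal",
                                        id = paste0("A", i))),
    lapply(1:3, function(i) make_stream(cumsum(c(0, rep(36000, 40))) + i,
                                        offset = 0L, label = "managed",
                                        id = paste0("B", i)))
  )
  event_cohort(streams)
}

test_that("training pools class events and respects the feature mode", {
  cohort <- two_class_cohort()
  m <- train_classifier(cohort, "ITD")
  dA <- m$densities[["personal"]]
  dB <- m$densities[["managed"]]
  expect_gt(density_at(dA, 60), density_at(dA, 36000))
  expect_gt(density_at(dB, 36000), density_at(dB, 60))
  # disjoint delay ranges leave each class's raw mass away from the other's
  iA <- findInterval(60, dA$bin_edges)
  iB <- findInterval(36000, dB$bin_edges)
  expect_equal(dA$density_raw[iB], 0)
  expect_equal(dB$density_raw[iA], 0)
})

test_that("TT scores depend on hours only, not on gap structure", {
  cohort <- two_class_cohort()
  m <- train_classifier(cohort, "TT")
  # same local hours, entirely different gaps (whole-day shifts)
  a <- make_stream(c(3600, 3600 + 86400 * 3, 3600 + 86400 * 9),
                   offset = 0L, id = "probe1")
  b <- make_stream(c(3600, 3600 + 86400, 3600 + 86400 * 2),
                   offset = 0L, id = "probe2")
  expect_equal(account_score(m, a), account_score(m, b))
})

test_that("scores are monotone in class density and finite off support", {
  cohort <- two_class_cohort()
  m <- train_classifier(cohort, "ITD")
  probe <- make_stream(cumsum(c(0, rep(60, 10))), offset = 0L, id = "p")
  sc <- account_score(m, probe)
  expect_true(all(is.finite(sc)))
  expect_gt(sc[["personal"]], sc[["managed"]])
  # features deep in the floor region of both classes stay finite
  far <- make_stream(cumsum(c(0, rep(5e6, 4))), offset = 0L, id = "far")
  expect_true(all(is.finite(account_score(m, far))))
})

test_that("MAP decisions respect priors and break ties deterministically", {
  # class densities sharing the long-delay bin at a 1:5 ratio, so the
  # log-likelihood gap at that delay is log(5), inside (0, log 9)
  cohort <- event_cohort(c(
    lapply(1:2, function(i) make_stream(
      cumsum(c(0, rep(60, 32), rep(36000, 8))) + i, offset = 0L,
      label = "personal", id = paste0("A", i))),
    lapply(1:2, function(i) make_stream(
      cumsum(c(0, rep(36000, 40))) + i, offset = 0L,
      label = "managed", id = paste0("B", i)))
  ))
  m <- train_classifier(cohort, "ITD")
  probe <- make_stream(c(0, 36000), offset = 0L, id = "edge")
  sc <- account_score(m, probe)
  gap <- sc[["managed"]] - sc[["personal"]]
  expect_gt(gap, 0)
  expect_lt(gap, log(9))
  expect_identical(classify_account(m, probe)$predicted, "managed")
  m_prior <- train_classifier(cohort, "ITD",
                              priors = c(personal = 0.9, managed = 0.1))
  expect_identical(classify_account(m_prior, probe)$predicted, "personal")
})

test_that("identical streams in both classes resolve by model order", {
  times <- cumsum(c(0, rep(100, 30)))
  cohort <- event_cohort(list(
    make_stream(times, offset = 0L, label = "personal", id = "a1"),
    make_stream(times, offset = 0L, label = "personal", id = "a2"),
    make_stream(times, offset = 0L, label = "managed", id = "b1"),
    make_stream(times, offset = 0L, label = "managed", id = "b2")
  ))
  rep1 <- loocv(cohort, "ITD")
  rep2 <- loocv(cohort, "ITD")
  expect_identical(rep1$accuracy, rep2$accuracy)
  preds <- vapply(rep1$outcomes, `[[`, character(1), "predicted")
  # every held-out account scores equal under both classes: first class wins
  expect_true(all(preds == "personal"))
})

test_that("LOOCV separates a well-separated synthetic cohort", {
  cohort <- small_cohort()
  accs <- vapply(c("JI", "ITD", "TT"), function(m) loocv(cohort, m)$accuracy,
                 numeric(1))
  expect_gte(accs[["JI"]], 0.85)
  expect_gte(accs[["JI"]], max(accs[["ITD"]], accs[["TT"]]))
  rep <- loocv(cohort, "JI")
  expect_equal(sum(rep$confusion), length(cohort))
  expect_equal(as.vector(rowSums(rep$confusion)),
               as.vector(rep$n_per_class))
  one_each <- event_cohort(unclass(cohort)[c(1, 9)])
  expect_error(loocv(one_each, "JI"), class = "chronoclass_bad_cohort")
})

test_that("stratified splits are reproducible and sized correctly", {
  cohort <- small_cohort()
  r1 <- split_evaluate(cohort, "JI", train_fraction = 0.5, n_repeats = 1L,
                       seed = 23L)
  r2 <- split_evaluate(cohort, "JI", train_fraction = 0.5, n_repeats = 1L,
                       seed = 23L)
  expect_identical(vapply(r1$outcomes, `[[`, character(1), "account_id"),
                   vapply(r2$outcomes, `[[`, character(1), "account_id"))
  expect_identical(r1$per_repeat, r2$per_repeat)
  # 0.5 of 2 accounts per class: one trains, one tests
  two_each <- event_cohort(unclass(cohort)[c(1, 2, 9, 10, 17, 18)])
  r3 <- split_evaluate(two_each, "JI", train_fraction = 0.5, n_repeats = 1L,
                       seed = 23L)
  expect_length(r3$outcomes, 3L)
  expect_error(split_evaluate(two_each, "JI", train_fraction = 0.99,
                              n_repeats = 1L, seed = 1L),
               class = "chronoclass_bad_split")
})

test_that("independence tests recover engineered dependence structure", {
  # event k sits in hour k and waits 3600 + k seconds: delay is a
  # strictly increasing function of the preceding hour
  mono <- event_cohort(list(
    make_stream(cumsum(c(0, 3600 + 0:22)), offset = 0L,
                label = "personal", id = "m1")
  ))
  res <- independence_tests(mono)
  expect_equal(res$kendall_tau, 1)
  expect_gt(res$pearson_r, 0.99)
  const <- event_cohort(list(
    make_stream(seq(0, by = 60, length.out = 30), offset = 0L,
                label = "bot", id = "c1")
  ))
  expect_error(independence_tests(const), class = "chronoclass_degenerate")
})
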