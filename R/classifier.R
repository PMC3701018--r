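# Naive-Bayes MAP classification of account type from empirical timing
# densities.  Four feature modes are supported:
#   ITD - inter-event delay marginal density (log-binned),
#   TT  - local posting-hour marginal mass,
#   JI  - joint of (delay, hour) assuming independence (product of marginals),
#   JNI - joint of (delay, hour) as a full 2-D histogram.
# Training pools all events of all training accounts of a class; an account
# is scored by the sum of log densities of its per-event features and
# assigned to the class with the highest score plus log prior.

FEATURE_MODES <- c("ITD", "TT", "JI", "JNI")

# Per-account feature tuples for a given mode.
account_features <- function(stream, mode) {
  if (mode == "TT") {
    list(hours = clock_features(stream)$local_hour)
  } else {
    ds <- compute_delays(stream)
    if (mode == "ITD") {
      list(delays = ds$delays)
    } else {
      list(delays = ds$delays, hours = ds$preceding_hour)
    }
  }
}

#' Train a timing-based naive-Bayes account classifier
#'
#' Pools the timing features of all training accounts of each class and
#' fits the per-class empirical densities required by the chosen feature
#' mode.  With uniform priors (the default) the MAP rule reduces to
#' maximum likelihood.
#'
#' @param cohort An [event_cohort()] of labelled accounts (each with >= 2
#'   events; hour-based modes additionally need a UTC offset).
#' @param mode Feature mode: `"ITD"`, `"TT"`, `"JI"` or `"JNI"`.
#' @param decades,n_bins Delay bin configuration, see [log_bin_edges()].
#' @param delay_floor,hour_floor Density floors, see [fit_delay_density()]
#'   and [fit_hour_density()].
#' @param priors Optional named per-class prior probabilities (summing to
#'   1); default uniform over the classes present.
#' @return A `timing_classifier` with one fitted density per class.
#' @export
train_classifier <- function(cohort, mode = c("JI", "ITD", "TT", "JNI"),
                             decades = c(0, 7), n_bins = 100L,
                             delay_floor = 1e-12, hour_floor = 1e-6,
                             priors = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "event_cohort"))
  labels <- cohort_labels(cohort)
  if ("unlabelled" %in% labels)
    stop_chrono("training cohort contains unlabelled accounts",
                "chronoclass_unlabelled")
  classes <- unique(labels)
  if (length(classes) < 2L)
    stop_chrono("need >= 2 classes to train", "chronoclass_bad_cohort")
  if (is.null(priors)) {
    priors <- stats::setNames(rep(1 / length(classes), length(classes)),
                              classes)
  } else {
    stopifnot(setequal(names(priors), classes),
              abs(sum(priors) - 1) < 1e-8)
    priors <- priors[classes]
  }
  densities <- lapply(classes, function(cl) {
    feats <- lapply(unclass(cohort)[labels == cl], account_features,
                    mode = mode)
    delays <- unlist(lapply(feats, `[[`, "delays"), use.names = FALSE)
    hours <- unlist(lapply(feats, `[[`, "hours"), use.names = FALSE)
    if (mode != "TT" && !length(delays))
      stop_chrono(sprintf("class %s has no delays", cl),
                  "chronoclass_empty_series")
    switch(mode,
      ITD = fit_delay_density(delays, decades, n_bins, delay_floor),
      TT = fit_hour_density(hours, hour_floor),
      JI = fit_joint(
        fit_delay_density(delays, decades, n_bins, delay_floor),
        fit_hour_density(hours[!is.na(hours)], hour_floor),
        mode = "independent"),
      JNI = fit_joint(
        fit_delay_density(delays, decades, n_bins, delay_floor),
        fit_hour_density(hours[!is.na(hours)], hour_floor),
        mode = "full2d", delays = delays, hours = hours)
    )
  })
  names(densities) <- classes
  structure(list(classes = classes, mode = mode, priors = priors,
                 densities = densities,
                 bin_config = list(decades = decades, n_bins = n_bins,
                                   delay_floor = delay_floor,
                                   hour_floor = hour_floor)),
            class = "timing_classifier")
}

#' @export
print.timing_classifier <- function(x, ...) {
  cat(sprintf("<timing_classifier> mode %s, classes: %s\n",
              x$mode, paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Per-class log-likelihood scores of one account
#'
#' The score of class `c` is the sum over the account's feature tuples of
#' the log class density (natural log).  Density floors guarantee finite
#' scores even for feature values never seen in training.
#'
#' @param model A [train_classifier()] result.
#' @param stream An [event_stream()].
#' @return Named numeric vector of per-class scores.
#' @export
account_score <- function(model, stream) {
  stopifnot(inherits(model, "timing_classifier"),
            inherits(stream, "event_stream"))
  f <- account_features(stream, model$mode)
  if (!length(f[[1L]]))
    stop_chrono(sprintf("account %s has no scorable features",
                        stream$account_id), "chronoclass_empty_series")
  vapply(model$classes, function(cl) {
    d <- model$densities[[cl]]
    vals <- switch(model$mode,
      ITD = density_at(d, f$delays),
      TT = density_at(d, f$hours),
      JI = ,
      JNI = density_at(d, q = f$delays, hour = f$hours))
    sum(log(vals))
  }, numeric(1))
}

#' Classify one account by the MAP rule
#'
#' @param model A [train_classifier()] result.
#' @param stream An [event_stream()].
#' @return A `classification_outcome`: `account_id`, `scores` (log
#'   likelihood plus log prior), `predicted`, `true_label`.  Ties break
#'   deterministically to the first class in model order.
#' @export
classify_account <- function(model, stream) {
  scores <- account_score(model, stream) + log(model$priors)
  structure(list(account_id = stream$account_id, scores = scores,
                 predicted = model$classes[which.max(scores)],
                 true_label = if (stream$label == "unlabelled") NA_character_
                              else stream$label),
            class = "classification_outcome")
}

evaluation_report <- function(mode, outcomes, classes,
                              per_repeat = NULL) {
  pred <- vapply(outcomes, `[[`, character(1), "predicted")
  truth <- vapply(outcomes, `[[`, character(1), "true_label")
  confusion <- table(factor(truth, classes), factor(pred, classes),
                     dnn = c("true", "predicted"))
  structure(list(mode = mode,
                 n_per_class = table(factor(truth, classes)),
                 accuracy = mean(pred == truth),
                 confusion = confusion,
                 per_repeat = per_repeat,
                 outcomes = outcomes),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> mode %s, accuracy %.3f\n",
              x$mode, x$accuracy))
  if (!is.null(x$per_repeat))
    cat(sprintf("  per-repeat: mean %.3f, sd %.3f (n = %d)\n",
                mean(x$per_repeat), stats::sd(x$per_repeat),
                length(x$per_repeat)))
  print(x$confusion)
  invisible(x)
}

#' Leave-one-out cross-validated classification
#'
#' For each account, trains on all remaining accounts and classifies the
#' held-out one; aggregates accuracy and the confusion matrix.
#'
#' @param cohort Labelled [event_cohort()], >= 2 accounts per class.
#' @param mode Feature mode, see [train_classifier()].
#' @param ... Passed on to [train_classifier()].
#' @return An `evaluation_report`.
#' @export
loocv <- function(cohort, mode = c("JI", "ITD", "TT", "JNI"), ...) {
  mode <- match.arg(mode)
  labels <- cohort_labels(cohort)
  if (any(table(labels) < 2L))
    stop_chrono("every class needs >= 2 accounts for LOOCV",
                "chronoclass_bad_cohort")
  classes <- unique(labels)
  outcomes <- lapply(seq_along(cohort), function(i) {
    model <- train_classifier(event_cohort(unclass(cohort)[-i]), mode, ...)
    classify_account(model, cohort[[i]])
  })
  evaluation_report(mode, outcomes, classes)
}

# Stratified per-class index split; returns train indices.
stratified_train_idx <- function(labels, train_fraction) {
  unlist(lapply(unique(labels), function(cl) {
    idx <- which(labels == cl)
    k <- max(1L, round(train_fraction * length(idx)))
    if (k >= length(idx))
      stop_chrono("train fraction leaves no test account in some class",
                  "chronoclass_bad_split")
    sample(idx, k)
  }), use.names = FALSE)
}

#' Repeated stratified train/test evaluation
#'
#' Splits each class independently into train and test accounts, trains on
#' the train split and classifies the test split, repeating with fresh
#' reshuffles; reports per-repeat accuracies and pooled confusion counts.
#'
#' @param cohort Labelled [event_cohort()].
#' @param mode Feature mode.
#' @param train_fraction Fraction of each class used for training, in
#'   (0, 1).
#' @param n_repeats Number of reshuffled repeats (default 10).
#' @param seed RNG seed for the splits.
#' @param ... Passed on to [train_classifier()].
#' @return An `evaluation_report` with `per_repeat` accuracies.
#' @export
split_evaluate <- function(cohort, mode = c("JI", "ITD", "TT", "JNI"),
                           train_fraction = 0.7, n_repeats = 10L,
                           seed = NULL, ...) {
  mode <- match.arg(mode)
  stopifnot(train_fraction > 0, train_fraction < 1)
  labels <- cohort_labels(cohort)
  classes <- unique(labels)
  local_seed(seed, {
    per_repeat <- numeric(n_repeats)
    outcomes <- list()
    for (r in seq_len(n_repeats)) {
      tr <- stratified_train_idx(labels, train_fraction)
      model <- train_classifier(event_cohort(unclass(cohort)[tr]), mode, ...)
      res <- lapply(unclass(cohort)[-tr], classify_account, model = model)
      per_repeat[r] <- mean(vapply(res, `[[`, character(1), "predicted") ==
                              vapply(res, `[[`, character(1), "true_label"))
      outcomes <- c(outcomes, res)
    }
    evaluation_report(mode, outcomes, classes, per_repeat = per_repeat)
  })
}

#' Label-shuffled chance baseline
#'
#' Randomly permutes the account labels before training and runs
#' leave-one-out cross-validation on the shuffled cohort, repeating
#' `n_repeats` times.  The resulting accuracy estimates the chance level
#' (about `1/K` for `K` balanced classes) against which the real
#' classifier is judged.
#'
#' @param cohort Labelled [event_cohort()].
#' @param mode Feature mode.
#' @param n_repeats Number of label permutations (default 10).
#' @param seed RNG seed.
#' @param ... Passed on to [train_classifier()].
#' @return An `evaluation_report` with `per_repeat` accuracies.
#' @export
shuffled_baseline <- function(cohort, mode = c("JI", "ITD", "TT", "JNI"),
                              n_repeats = 10L, seed = NULL, ...) {
  mode <- match.arg(mode)
  labels <- cohort_labels(cohort)
  classes <- unique(labels)
  local_seed(seed, {
    per_repeat <- numeric(n_repeats)
    outcomes <- list()
    for (r in seq_len(n_repeats)) {
      perm <- sample(labels)
      shuffled <- event_cohort(lapply(seq_along(cohort), function(i) {
        s <- cohort[[i]]
        s$label <- perm[i]
        s
      }))
      rep_r <- loocv(shuffled, mode, ...)
      per_repeat[r] <- rep_r$accuracy
      outcomes <- c(outcomes, rep_r$outcomes)
    }
    evaluation_report(mode, outcomes, classes, per_repeat = per_repeat)
  })
}

#' Delay / hour independence tests per class
#'
#' Pools the `(delay, preceding hour)` pairs of every account of each class
#' and reports Pearson's r and Kendall's tau between the two variables,
#' with the p-values of the corresponding correlation tests.  Low values
#' support the independence assumption behind the product-form (JI)
#' feature model.
#'
#' @param cohort Labelled [event_cohort()] of localised accounts.
#' @return Data frame with one row per class: `class`, `n`, `pearson_r`,
#'   `pearson_p`, `kendall_tau`, `kendall_p`.
#' @export
independence_tests <- function(cohort) {
  labels <- cohort_labels(cohort)
  res <- lapply(unique(labels), function(cl) {
    pairs <- lapply(unclass(cohort)[labels == cl], function(s) {
      ds <- compute_delays(s)
      ok <- !is.na(ds$preceding_hour)
      cbind(ds$delays[ok], ds$preceding_hour[ok])
    })
    m <- do.call(rbind, pairs)
    if (nrow(m) < 3L)
      stop_chrono(sprintf("class %s has < 3 (delay, hour) pairs", cl),
                  "chronoclass_bad_cohort")
    if (stats::sd(m[, 1L]) == 0 || stats::sd(m[, 2L]) == 0)
      stop_chrono(sprintf("class %s: constant column, correlation undefined",
                          cl), "chronoclass_degenerate")
    pe <- suppressWarnings(stats::cor.test(m[, 1L], m[, 2L],
                                           method = "pearson"))
    ke <- suppressWarnings(stats::cor.test(m[, 1L], m[, 2L],
                                           method = "kendall"))
    data.frame(class = cl, n = nrow(m),
               pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
               kendall_tau = unname(ke$estimate), kendall_p = ke$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
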