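# Event-stream ingestion, validation, timezone localisation and basic
# timing features (inter-event delays, clock read-outs).

ACCOUNT_LABELS <- c("personal", "managed", "bot", "unlabelled")

#' Construct an event stream for one account
#'
#' An event stream holds the time-ordered posting timestamps of a single
#' account, the account's fixed UTC offset (minutes) and an optional class
#' label.  Timestamps are stored as numeric seconds since the Unix epoch
#' (UTC); localisation is a fixed per-account offset, deliberately ignoring
#' daylight-saving rules, since each account advertises a single timezone.
#'
#' @param account_id Character scalar identifying the account.
#' @param t_utc Numeric vector of event times, seconds since the Unix epoch
#'   (UTC).  Sorted internally; sub-second parts are truncated.
#' @param utc_offset_min Signed UTC offset in minutes, or `NA` when the
#'   account did not declare a timezone.  Must satisfy `|offset| <= 840`.
#' @param label One of `"personal"`, `"managed"`, `"bot"`, `"unlabelled"`.
#' @param history_cap Keep at most this many most-recent events
#'   (default 800, mirroring a typical per-account harvest cap).
#' @return An object of class `event_stream`.
#' @export
event_stream <- function(account_id, t_utc, utc_offset_min = NA_integer_,
                         label = "unlabelled", history_cap = 800L) {
  stopifnot(is.character(account_id), length(account_id) == 1L,
            is.numeric(t_utc))
  label <- match.arg(label, ACCOUNT_LABELS)
  if (!is.na(utc_offset_min)) {
    utc_offset_min <- as.integer(utc_offset_min)
    if (abs(utc_offset_min) > 14L * 60L)
      stop_chrono(sprintf("utc_offset_min %d outside +/-840 minutes",
                          utc_offset_min), "chronoclass_bad_offset")
  }
  t_utc <- sort(floor(as.numeric(t_utc)))
  if (length(t_utc) && !all(is.finite(t_utc)))
    stop_chrono("non-finite event times", "chronoclass_bad_time")
  if (is.finite(history_cap) && length(t_utc) > history_cap)
    t_utc <- t_utc[(length(t_utc) - history_cap + 1L):length(t_utc)]
  structure(
    list(account_id = account_id, label = label, t_utc = t_utc,
         utc_offset_min = if (is.na(utc_offset_min)) NA_integer_ else utc_offset_min),
    class = "event_stream"
  )
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("<event_stream> %s [%s], %d events, offset %s min\n",
              x$account_id, x$label, length(x$t_utc),
              if (is.na(x$utc_offset_min)) "?" else x$utc_offset_min))
  invisible(x)
}

n_events <- function(stream) length(stream$t_utc)

has_offset <- function(stream) !is.na(stream$utc_offset_min)

#' Bundle event streams into a cohort
#'
#' @param streams List of [event_stream()] objects.
#' @return An object of class `event_cohort` (a named list of streams).
#' @export
event_cohort <- function(streams) {
  stopifnot(is.list(streams),
            all(vapply(streams, inherits, logical(1), "event_stream")))
  ids <- vapply(streams, `[[`, character(1), "account_id")
  if (anyDuplicated(ids))
    stop_chrono("duplicate account_id in cohort", "chronoclass_dup_account")
  names(streams) <- ids
  structure(streams, class = "event_cohort")
}

#' @export
print.event_cohort <- function(x, ...) {
  labs <- vapply(x, `[[`, character(1), "label")
  cat(sprintf("<event_cohort> %d accounts (%s)\n", length(x),
              paste(sprintf("%s: %d", names(table(labs)), table(labs)),
                    collapse = ", ")))
  invisible(x)
}

cohort_labels <- function(cohort) vapply(cohort, `[[`, character(1), "label")

parse_iso_times <- function(x) {
  if (is.numeric(x)) return(floor(as.numeric(x)))
  x <- trimws(as.character(x))
  canon <- sub("Z$", "", sub(" ", "T", x))
  out <- as.POSIXct(canon, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  # date-only records are midnight UTC
  miss <- is.na(out) & grepl("^\\d{4}-\\d{2}-\\d{2}$", canon)
  if (any(miss))
    out[miss] <- as.POSIXct(canon[miss], tz = "UTC", format = "%Y-%m-%d")
  floor(as.numeric(out))
}

#' Parse per-account event records into a cohort
#'
#' Accepts a data frame or a path to a JSON-lines / CSV file with columns
#' `account_id`, `t_utc` (ISO-8601 UTC or epoch seconds), `utc_offset_min`
#' (may be missing/empty) and optional `label`.  Records are grouped by
#' account, sorted in time and deduplicated; accounts lacking an offset are
#' kept but flagged (their `utc_offset_min` is `NA`) so that
#' [filter_accounts()] can discard them.
#'
#' @param source Data frame, or path to a `.jsonl`/`.json` or `.csv` file.
#' @param history_cap Per-account cap on retained (most recent) events.
#' @return An [event_cohort()].
#' @export
parse_events <- function(source, history_cap = 800L) {
  df <- if (is.data.frame(source)) {
    source
  } else if (is.character(source) && length(source) == 1L) {
    if (grepl("\\.(jsonl|json|ndjson)$", source, ignore.case = TRUE)) {
      jsonlite::stream_in(file(source), verbose = FALSE)
    } else {
      utils::read.csv(source, stringsAsFactors = FALSE)
    }
  } else {
    stop_chrono("source must be a data frame or a file path",
                "chronoclass_bad_source")
  }
  req <- c("account_id", "t_utc")
  if (!all(req %in% names(df)))
    stop_chrono(paste("missing columns:",
                      paste(setdiff(req, names(df)), collapse = ", ")),
                "chronoclass_bad_source")
  if (!"utc_offset_min" %in% names(df)) df$utc_offset_min <- NA_integer_
  if (!"label" %in% names(df)) df$label <- "unlabelled"
  df$label[is.na(df$label) | df$label == ""] <- "unlabelled"

  t_parsed <- parse_iso_times(df$t_utc)
  if (anyNA(t_parsed)) {
    bad <- which(is.na(t_parsed))
    stop_chrono(sprintf("malformed timestamp at record(s) %s (e.g. %s)",
                        paste(utils::head(bad, 5L), collapse = ", "),
                        df$t_utc[bad[1L]]),
                "chronoclass_bad_time")
  }
  df$t_utc <- t_parsed
  df$utc_offset_min <- suppressWarnings(as.integer(df$utc_offset_min))

  key <- paste(df$account_id, df$t_utc, df$utc_offset_min, df$label)
  if (anyDuplicated(key)) {
    warning(sprintf("dropped %d duplicate record(s)", sum(duplicated(key))))
    df <- df[!duplicated(key), , drop = FALSE]
  }

  streams <- lapply(split(df, df$account_id), function(d) {
    offs <- unique(d$utc_offset_min[!is.na(d$utc_offset_min)])
    if (length(offs) > 1L)
      stop_chrono(sprintf("conflicting utc_offset_min for account %s",
                          d$account_id[1L]), "chronoclass_bad_offset")
    labs <- setdiff(unique(d$label), "unlabelled")
    event_stream(
      account_id = d$account_id[1L],
      t_utc = d$t_utc,
      utc_offset_min = if (length(offs)) offs else NA_integer_,
      label = if (length(labs) == 1L) labs else "unlabelled",
      history_cap = history_cap
    )
  })
  event_cohort(unname(streams))
}

#' Write a cohort back to disk
#'
#' Emits the same dialect [parse_events()] reads, deterministically sorted
#' by `account_id` then `t_utc` so repeated writes are byte-identical.
#'
#' @param cohort An [event_cohort()].
#' @param path Output file path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_events <- function(cohort, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  rows <- do.call(rbind, lapply(cohort, function(s) {
    data.frame(
      account_id = s$account_id,
      label = if (s$label == "unlabelled") NA_character_ else s$label,
      t_utc = format(as.POSIXct(s$t_utc, origin = "1970-01-01", tz = "UTC"),
                     "%Y-%m-%dT%H:%M:%SZ"),
      utc_offset_min = s$utc_offset_min,
      stringsAsFactors = FALSE
    )
  }))
  rows <- rows[order(rows$account_id, rows$t_utc), , drop = FALSE]
  if (format == "csv") {
    utils::write.csv(rows, path, row.names = FALSE, na = "")
  } else {
    con <- file(path, open = "wb")
    on.exit(close(con))
    for (i in seq_len(nrow(rows))) {
      rec <- as.list(rows[i, , drop = FALSE])
      if (is.na(rec$label)) rec$label <- NULL
      if (is.na(rec$utc_offset_min)) rec$utc_offset_min <- NULL
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Inter-event delays with preceding local hour
#'
#' Computes the seconds elapsed between consecutive events of one account.
#' Zero gaps (same-second posts) are floored to 1 s so downstream
#' log-binned densities stay defined and series lengths stay predictable.
#' Each delay is tagged with the local hour of the event that *precedes*
#' it, the conditioning variable of the hour-resolved predictor.
#'
#' @param stream An [event_stream()] with at least two events.
#' @param floor_s Lower floor applied to each gap, seconds (default 1).
#' @return A `delay_series`: list with `delays` (positive seconds) and
#'   `preceding_hour` (0-23 integers, `NA` when the stream has no offset).
#' @export
compute_delays <- function(stream, floor_s = 1) {
  stopifnot(inherits(stream, "event_stream"))
  if (n_events(stream) < 2L)
    stop_chrono(sprintf("account %s: need >= 2 events for delays",
                        stream$account_id), "chronoclass_empty_series")
  delays <- pmax(floor_s, diff(stream$t_utc))
  preceding_hour <- if (has_offset(stream)) {
    t_local <- stream$t_utc + stream$utc_offset_min * 60
    hour_of_day(t_local[-length(t_local)])
  } else {
    rep(NA_integer_, length(delays))
  }
  structure(list(delays = delays, preceding_hour = preceding_hour),
            class = "delay_series")
}

#' Local clock features of an event stream
#'
#' @param stream An [event_stream()] with a known UTC offset.
#' @return A `clock_features` list with `local_hour` (0-23) and `weekday`
#'   (ISO convention, Monday = 1) per event.
#' @export
clock_features <- function(stream) {
  stopifnot(inherits(stream, "event_stream"))
  if (!has_offset(stream))
    stop_chrono(sprintf(
      "account %s has no UTC offset; drop it with filter_accounts(require_offset = TRUE)",
      stream$account_id), "chronoclass_missing_offset")
  t_local <- stream$t_utc + stream$utc_offset_min * 60
  structure(list(local_hour = hour_of_day(t_local),
                 weekday = iso_weekday(t_local)),
            class = "clock_features")
}

#' Filter a cohort on event count and timezone availability
#'
#' Accounts that never declared a timezone cannot be localised, so every
#' clock-based analysis discards them; the discarded ids are attached as an
#' attribute for reporting.
#'
#' @param cohort An [event_cohort()].
#' @param min_events Minimum number of events to retain an account.
#' @param require_offset Drop accounts whose UTC offset is unknown.
#' @return Filtered [event_cohort()] with attribute `"discarded"` (ids).
#' @export
filter_accounts <- function(cohort, min_events = 2L, require_offset = TRUE) {
  stopifnot(inherits(cohort, "event_cohort"), is_count(min_events))
  keep <- vapply(cohort, function(s) {
    n_events(s) >= min_events && (!require_offset || has_offset(s))
  }, logical(1))
  out <- event_cohort(unclass(cohort)[keep])
  attr(out, "discarded") <- names(cohort)[!keep]
  out
}
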