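# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded helpers do not
#' perturb an enclosing simulation.
#' @noRd
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_chrono <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "chronoclass_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Hour of day (0-23) from local epoch seconds
#' @noRd
hour_of_day <- function(t_local) {
  as.integer((floor(t_local) %% 86400) %/% 3600)
}

#' ISO weekday (Monday = 1 ... Sunday = 7) from local epoch seconds.
#' The Unix epoch fell on a Thursday (ISO day 4).
#' @noRd
iso_weekday <- function(t_local) {
  as.integer(((floor(t_local) %/% 86400) + 3) %% 7 + 1)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}
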