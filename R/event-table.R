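#' Idealized event table
#'
#' The interchange object between idealization, dwell analysis and rate
#' estimation: a sequence of contiguous dwells, each labelled `"open"` or
#' `"closed"`, with start times and durations in ms. Classes must strictly
#' alternate and events must tile the record without gaps or overlap.
#'
#' @param class Character vector of dwell classes (`"open"`/`"closed"`),
#'   strictly alternating.
#' @param duration_ms Dwell durations in ms, all > 0.
#' @param start_ms Optional start times; defaults to the cumulative sum of
#'   durations starting at `t0_ms`.
#' @param t0_ms Record start time (ms).
#' @param dead_time Dead time already imposed on the table (ms); 0 for raw
#'   idealizations.
#' @param sampling_rate Sampling rate of the source record (Hz), if any.
#' @return A data.frame of class `event_table` with columns `start_ms`,
#'   `duration_ms`, `class`, and attributes `dead_time` and
#'   `sampling_rate`.
#' @export
event_table <- function(class, duration_ms, start_ms = NULL, t0_ms = 0,
                        dead_time = 0, sampling_rate = NA_real_) {
  class <- as.character(class)
  duration_ms <- as.numeric(duration_ms)
  if (length(class) != length(duration_ms)) {
    stop("`class` and `duration_ms` lengths differ", call. = FALSE)
  }
  if (length(class) && !all(class %in% c("open", "closed"))) {
    stop("classes must be 'open' or 'closed'", call. = FALSE)
  }
  if (any(!is.finite(duration_ms)) || any(duration_ms <= 0)) {
    stop("durations must be finite and > 0", call. = FALSE)
  }
  if (length(class) > 1L && any(class[-1L] == class[-length(class)])) {
    stop("classes must strictly alternate", call. = FALSE)
  }
  if (is.null(start_ms)) {
    start_ms <- if (length(duration_ms)) {
      t0_ms + c(0, cumsum(duration_ms)[-length(duration_ms)])
    } else {
      numeric(0)
    }
  } else {
    start_ms <- as.numeric(start_ms)
    if (length(start_ms) != length(class)) {
      stop("`start_ms` length mismatch", call. = FALSE)
    }
    if (length(class) > 1L) {
      gap <- start_ms[-1L] - (start_ms[-length(start_ms)] +
                                duration_ms[-length(duration_ms)])
      if (any(abs(gap) > 1e-6)) {
        stop("events must be contiguous and non-overlapping", call. = FALSE)
      }
    }
  }
  out <- data.frame(start_ms = start_ms, duration_ms = duration_ms,
                    class = class, stringsAsFactors = FALSE)
  attr(out, "dead_time") <- as.numeric(dead_time)
  attr(out, "sampling_rate") <- as.numeric(sampling_rate)
  class(out) <- c("event_table", "data.frame")
  out
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table: %d dwells, %.4g ms total, dead time %g ms>\n",
              nrow(x), sum(x$duration_ms), attr(x, "dead_time")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Total record duration of an event table (ms)
#' @param events An [event_table()].
#' @export
total_duration <- function(events) sum(events$duration_ms)

# Drop first and last dwell (right/left-censored at the record boundaries).
drop_censored <- function(events) {
  if (nrow(events) <= 2L) {
    return(events[integer(0), , drop = FALSE])
  }
  out <- events[-c(1L, nrow(events)), , drop = FALSE]
  attributes(out)[c("dead_time", "sampling_rate")] <-
    attributes(events)[c("dead_time", "sampling_rate")]
  class(out) <- c("event_table", "data.frame")
  out
}

#' Dwell durations of one class
#'
#' @param events An [event_table()].
#' @param class `"open"` or `"closed"`.
#' @param drop_boundary Exclude the censored first/last dwell of the
#'   record (default TRUE, matching standard dwell-fitting practice).
#' @return Numeric vector of durations (ms).
#' @export
dwells_of_class <- function(events, class, drop_boundary = TRUE) {
  class <- match.arg(class, c("open", "closed"))
  if (drop_boundary) events <- drop_censored(events)
  events$duration_ms[events$class == class]
}
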