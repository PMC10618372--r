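#' Read and write idealized event tables
#'
#' Event tables are exchanged as tab-separated text with a header
#' (`start_ms`, `duration_ms`, `class`). Strict alternation, positivity
#' and contiguity are validated on read; violations are reported with the
#' offending line number.
#'
#' @param events An [event_table()].
#' @param path File path.
#' @return `read_event_table` returns an [event_table()];
#'   `write_event_table` returns `path` invisibly.
#' @export
write_event_table <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  df <- as.data.frame(events)[, c("start_ms", "duration_ms", "class")]
  if (requireNamespace("data.table", quietly = TRUE)) {
    data.table::fwrite(df, path, sep = "\t")
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  if (requireNamespace("data.table", quietly = TRUE)) {
    df <- as.data.frame(suppressWarnings(
      data.table::fread(path, sep = "\t",
                        colClasses = list(character = "class"))))
  } else {
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  }
  need <- c("start_ms", "duration_ms", "class")
  if (!all(need %in% names(df))) {
    stop("parse error: header must contain start_ms, duration_ms, class",
         call. = FALSE)
  }
  if (nrow(df) == 0L) {
    return(event_table(character(0), numeric(0)))
  }
  bad <- which(!df$class %in% c("open", "closed"))
  if (length(bad)) {
    stop(sprintf("parse error at line %d: class must be 'open' or 'closed'",
                 bad[1L] + 1L), call. = FALSE)
  }
  bad <- which(!is.finite(df$duration_ms) | df$duration_ms <= 0)
  if (length(bad)) {
    stop(sprintf("parse error at line %d: non-positive duration", bad[1L] + 1L),
         call. = FALSE)
  }
  if (nrow(df) > 1L) {
    same <- which(df$class[-1L] == df$class[-nrow(df)])
    if (length(same)) {
      stop(sprintf("parse error at line %d: classes do not alternate",
                   same[1L] + 2L), call. = FALSE)
    }
    gap <- df$start_ms[-1L] - (df$start_ms[-nrow(df)] + df$duration_ms[-nrow(df)])
    off <- which(abs(gap) > 1e-6)
    if (length(off)) {
      stop(sprintf("parse error at line %d: events overlap or leave a gap",
                   off[1L] + 2L), call. = FALSE)
    }
  }
  event_table(df$class, df$duration_ms, start_ms = df$start_ms)
}

#' Read and write kinetic schemes as JSON
#'
#' Schemes are serialized as structured text: state list, per-state class,
#' rate entries (`from`, `to`, `rate` in 1/ms), conductance (pS), reversal
#' (mV), reference temperature (degrees C), forward-transition list and
#' Q10 map.
#'
#' @param scheme A [kinetic_scheme()].
#' @param path File path.
#' @return `read_scheme` returns a `kinetic_scheme`; `write_scheme`
#'   returns `path` invisibly.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  nz <- which(scheme$Q > 0, arr.ind = TRUE)
  obj <- list(
    states = scheme$states,
    class_of_state = scheme$class_of_state,
    rates = data.frame(from = scheme$states[nz[, 1L]],
                       to = scheme$states[nz[, 2L]],
                       rate = scheme$Q[nz]),
    conductance_pS = scheme$conductance,
    vrev_mV = scheme$vrev,
    reference_temperature_C = scheme$reference_temperature,
    forward = as.data.frame(scheme$forward),
    q10_forward = as.list(scheme$q10_forward)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  states <- obj$states
  n <- length(states)
  Q <- matrix(0, n, n, dimnames = list(states, states))
  r <- obj$rates
  Q[cbind(match(r$from, states), match(r$to, states))] <- r$rate
  q10 <- unlist(obj$q10_forward)
  fw <- if (length(obj$forward)) as.matrix(obj$forward) else NULL
  kinetic_scheme(states, obj$class_of_state, Q,
                 conductance = obj$conductance_pS, vrev = obj$vrev_mV,
                 reference_temperature = obj$reference_temperature_C,
                 forward = fw, q10_forward = q10)
}

#' Read and write dwell mixtures as JSON
#' @param mixture A [dwell_mixture()].
#' @param path File path.
#' @export
write_mixture <- function(mixture, path) {
  stopifnot(inherits(mixture, "dwell_mixture"))
  jsonlite::write_json(unclass(mixture), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_mixture
#' @export
read_mixture <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dwell_mixture(obj$class, obj$taus, obj$areas, obj$temperature)
}

#' Read and write current traces as two-column delimited text
#'
#' Traces are stored as `time_s` and `current_pA` columns; metadata
#' (sampling rate, temperature, seed, ...) travels in `#`-prefixed header
#' lines.
#'
#' @param trace A [current_trace()].
#' @param path File path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate %.10g", trace$sampling_rate), con)
  md <- trace$metadata
  for (nm in names(md)) {
    if (is.numeric(md[[nm]]) || is.character(md[[nm]])) {
      writeLines(sprintf("# %s %s", nm, paste(md[[nm]], collapse = " ")), con)
    }
  }
  writeLines("time_s\tcurrent_pA", con)
  t_s <- (seq_along(trace$samples) - 1L) / trace$sampling_rate
  writeLines(sprintf("%.8f\t%.6g", t_s, trace$samples), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path, n = 64L)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    parts <- strsplit(sub("^#\\s*", "", h), "\\s+")[[1L]]
    if (length(parts) >= 2L) {
      val <- suppressWarnings(as.numeric(parts[-1L]))
      meta[[parts[1L]]] <- if (any(is.na(val))) paste(parts[-1L], collapse = " ") else val
    }
  }
  if (is.null(meta$sampling_rate)) {
    stop("parse error: missing '# sampling_rate' header", call. = FALSE)
  }
  df <- utils::read.delim(path, comment.char = "#")
  current_trace(df$current_pA, meta$sampling_rate,
                metadata = meta[setdiff(names(meta), "sampling_rate")])
}

#' Run manifest
#'
#' Records everything needed to reproduce a pipeline invocation: the
#' command, the configuration snapshot, all seeds, package version and
#' input/output paths.
#'
#' @param command Command or function name.
#' @param config Configuration object (list-like).
#' @param seeds Named or unnamed integer vector of seeds used.
#' @param inputs,outputs Character vectors of paths.
#' @param path Optional path to write the manifest JSON to.
#' @return The manifest as a list (invisibly if written).
#' @export
run_manifest <- function(command, config = list(), seeds = integer(0),
                         inputs = character(0), outputs = character(0),
                         path = NULL) {
  man <- list(
    command = command,
    package = "pvngate",
    version = as.character(utils::packageVersion("pvngate")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = if (!is.null(names(seeds))) as.list(seeds) else seeds,
    config = config,
    inputs = inputs,
    outputs = outputs
  )
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    return(invisible(man))
  }
  man
}
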