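#' Two-level amplitude model from the all-points histogram
#'
#' Describes a single-channel record as two Gaussian amplitude components
#' (closed and open levels with per-level noise SD), estimated from the
#' all-points amplitude distribution by Gaussian-mixture fitting followed
#' by a trimmed refinement that re-estimates each level from the samples
#' within 2.5 SD of it (this removes the bias that filter-attenuated brief
#' events otherwise put on the component means).
#'
#' @param trace A [current_trace()] with at least 1000 samples.
#' @param baseline Optional known closed level (pA); the component nearer
#'   this value is labelled closed. Default 0 (pipette current is offset
#'   to zero around the closed level in cell-attached records).
#' @param max_points Histogram fitting uses at most this many samples,
#'   taken evenly across the record (deterministic).
#' @return A list of class `amplitude_model`: `closed_level`, `open_level`,
#'   `sd_closed`, `sd_open`, `snr` (separation over mean SD),
#'   `open_detected` (FALSE when the histogram is effectively unimodal,
#'   with a warning).
#' @export
fit_amplitude_model <- function(trace, baseline = 0, max_points = 50000L) {
  stopifnot(inherits(trace, "current_trace"))
  x <- trace$samples
  if (length(x) < 1000L) stop("trace too short (< 1000 samples)", call. = FALSE)
  if (length(x) > max_points) {
    x <- x[seq(1L, length(x), length.out = max_points)]
  }
  # two-component Gaussian EM (mclust), deterministically initialized by a
  # k-means split seeded at the 10th/90th amplitude percentiles
  centers <- matrix(stats::quantile(x, c(0.1, 0.9)), ncol = 1L)
  unimodal <- FALSE
  mu <- NULL
  if (abs(diff(centers)) < 1e-12) {
    unimodal <- TRUE
  } else {
    km <- suppressWarnings(stats::kmeans(x, centers = centers))
    mu_km <- as.numeric(km$centers)
    sd_km <- vapply(1:2, function(g) stats::sd(x[km$cluster == g]), numeric(1))
    sd_km[!is.finite(sd_km)] <- 0
    if (max(sd_km) < 1e-8 * abs(diff(mu_km))) {
      # (near-)noiseless two-level record: k-means split is exact
      mu <- mu_km
      sd_ <- pmax(sd_km, 1e-9 * abs(diff(mu_km)))
    } else {
      fit <- try(mclust::meV(data = x, z = mclust::unmap(km$cluster)),
                 silent = TRUE)
      if (!inherits(fit, "try-error") &&
          all(is.finite(fit$parameters$mean)) &&
          all(is.finite(fit$parameters$variance$sigmasq))) {
        mu <- as.numeric(fit$parameters$mean)
        sd_ <- sqrt(fit$parameters$variance$sigmasq)
      } else {
        mu <- mu_km
        sd_ <- pmax(sd_km, 1e-12)
      }
    }
  }
  if (!unimodal) {
    if (length(sd_) == 1L) sd_ <- rep(sd_, 2L)
    # unimodality decision from the mixture fit itself: a genuine two-level
    # record separates its components well beyond their own widths
    if (abs(diff(mu)) < 3 * mean(sd_)) unimodal <- TRUE
  }
  if (!unimodal) {
    # trimmed refinement: hard-assign, keep samples close to their level
    for (iter in 1:3) {
      d1 <- abs(x - mu[1L]) / sd_[1L]
      d2 <- abs(x - mu[2L]) / sd_[2L]
      a1 <- d1 <= d2
      k1 <- a1 & abs(x - mu[1L]) <= 2.5 * sd_[1L]
      k2 <- !a1 & abs(x - mu[2L]) <= 2.5 * sd_[2L]
      if (sum(k1) < 50L || sum(k2) < 50L) break
      mu <- c(mean(x[k1]), mean(x[k2]))
      sd_ <- c(stats::sd(x[k1]), stats::sd(x[k2]))
      sd_[!is.finite(sd_)] <- 0
      sd_ <- pmax(sd_, 1e-9 * max(abs(diff(mu)), 1e-3))
    }
  }
  if (unimodal) {
    warning("amplitude histogram is effectively unimodal; no open level detected")
    return(structure(list(closed_level = stats::median(x),
                          open_level = NA_real_,
                          sd_closed = stats::sd(x), sd_open = NA_real_,
                          snr = 0, open_detected = FALSE),
                     class = "amplitude_model"))
  }
  closed_first <- abs(mu[1L] - baseline) <= abs(mu[2L] - baseline)
  ic <- if (closed_first) 1L else 2L
  io <- if (closed_first) 2L else 1L
  structure(list(closed_level = mu[ic], open_level = mu[io],
                 sd_closed = sd_[ic], sd_open = sd_[io],
                 snr = abs(mu[io] - mu[ic]) / mean(sd_),
                 open_detected = TRUE),
            class = "amplitude_model")
}

#' @export
print.amplitude_model <- function(x, ...) {
  cat(sprintf(
    "<amplitude_model: closed %.3g pA (sd %.3g), open %s, SNR %.2f>\n",
    x$closed_level, x$sd_closed,
    if (x$open_detected) sprintf("%.3g pA (sd %.3g)", x$open_level, x$sd_open)
    else "not detected", x$snr))
  invisible(x)
}

#' Segmental-k-means idealization of a current trace
#'
#' Alternates (i) the most-likely open/closed sample path given the current
#' levels, noise SDs and transition probabilities (a two-state Viterbi
#' pass) with (ii) re-estimation of levels, SDs and transition
#' probabilities from the assignment, until fewer than `tol_frac` of the
#' samples change class or `max_iter` is reached (with a warning on
#' non-convergence). The resulting sample path is run-length encoded into
#' an alternating [event_table()]; no dead time is imposed here (see
#' [apply_dead_time()]).
#'
#' @param trace A [current_trace()].
#' @param model An `amplitude_model` with a detected open level (used to
#'   seed the levels).
#' @param max_iter Iteration cap.
#' @param tol_frac Convergence threshold on the fraction of reassigned
#'   samples.
#' @return An [event_table()] (dead time 0) with the record's sampling rate
#'   attached.
#' @export
skm_idealize <- function(trace, model, max_iter = 50L, tol_frac = 0.001) {
  stopifnot(inherits(trace, "current_trace"),
            inherits(model, "amplitude_model"))
  if (!isTRUE(model$open_detected)) {
    stop("amplitude model has no open level; cannot idealize", call. = FALSE)
  }
  x <- trace$samples
  n <- length(x)
  mu <- c(model$closed_level, model$open_level)
  sd_ <- pmax(c(model$sd_closed, model$sd_open), 1e-6)
  p_switch <- c(0.05, 0.05)
  prev <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ltr <- log(matrix(c(1 - p_switch[1L], p_switch[1L],
                        p_switch[2L], 1 - p_switch[2L]),
                      2L, 2L, byrow = TRUE))
    path <- .viterbi2(x, mu, sd_, ltr, log(c(0.5, 0.5)))
    if (!is.null(prev)) {
      changed <- mean(path != prev)
      if (changed < tol_frac) { converged <- TRUE; prev <- path; break }
    }
    prev <- path
    n1 <- sum(path)
    if (n1 == 0L || n1 == n) break  # degenerate assignment; keep model
    mu <- c(mean(x[path == 0L]), mean(x[path == 1L]))
    sd_ <- pmax(c(stats::sd(x[path == 0L]), stats::sd(x[path == 1L])), 1e-6)
    tr01 <- sum(path[-1L] == 1L & path[-n] == 0L)
    tr10 <- sum(path[-1L] == 0L & path[-n] == 1L)
    p_switch <- pmin(pmax(c(tr01 / max(n - n1, 1L), tr10 / max(n1, 1L)),
                          1e-6), 0.5)
  }
  if (!converged && it == max_iter) {
    warning("SKM did not converge in ", max_iter, " iterations; returning best assignment")
  }
  r <- rle(prev)
  dt_ms <- 1000 / trace$sampling_rate
  event_table(ifelse(r$values == 1L, "open", "closed"),
              r$lengths * dt_ms, dead_time = 0,
              sampling_rate = trace$sampling_rate)
}

#' Half-amplitude threshold idealization
#'
#' Fast fallback idealizer: samples are assigned open when beyond the
#' midpoint between the closed and open levels.
#'
#' @inheritParams skm_idealize
#' @return An [event_table()].
#' @export
threshold_idealize <- function(trace, model) {
  stopifnot(inherits(trace, "current_trace"),
            inherits(model, "amplitude_model"))
  if (!isTRUE(model$open_detected)) {
    stop("amplitude model has no open level; cannot idealize", call. = FALSE)
  }
  thr <- (model$closed_level + model$open_level) / 2
  if (model$open_level > model$closed_level) {
    path <- trace$samples > thr
  } else {
    path <- trace$samples < thr
  }
  r <- rle(as.integer(path))
  dt_ms <- 1000 / trace$sampling_rate
  event_table(ifelse(r$values == 1L, "open", "closed"),
              r$lengths * dt_ms, dead_time = 0,
              sampling_rate = trace$sampling_rate)
}

#' Impose a dead time on an event table
#'
#' Dwells shorter than the dead time cannot be resolved by the recording
#' chain; they are removed and their duration absorbed into the current
#' resolved dwell (standard concatenation). The output alternates, all
#' durations are >= the dead time, and the total record duration is
#' conserved.
#'
#' @param events An [event_table()].
#' @param dead_time Dead time in ms (default 0.3, three 0.1-ms intervals of
#'   the emulated acquisition chain).
#' @return An [event_table()] with the `dead_time` attribute set.
#' @export
apply_dead_time <- function(events, dead_time = 0.3) {
  if (dead_time < 0) stop("parameter error: dead_time must be >= 0", call. = FALSE)
  n <- nrow(events)
  if (n == 0L || dead_time == 0) {
    attr(events, "dead_time") <- dead_time
    return(events)
  }
  dur <- events$duration_ms
  cls <- events$class
  # find the first resolvable dwell; unresolvable leading dwells merge into it
  i0 <- which(dur >= dead_time)[1L]
  if (is.na(i0)) {
    stop("no dwell reaches the dead time; record unresolvable", call. = FALSE)
  }
  out_cls <- character(n)
  out_dur <- numeric(n)
  m <- 0L
  cur_cls <- cls[i0]
  cur_dur <- sum(dur[seq_len(i0)])
  i <- i0 + 1L
  while (i <= n) {
    if (dur[i] < dead_time || cls[i] == cur_cls) {
      cur_dur <- cur_dur + dur[i]
    } else {
      m <- m + 1L
      out_cls[m] <- cur_cls
      out_dur[m] <- cur_dur
      cur_cls <- cls[i]
      cur_dur <- dur[i]
    }
    i <- i + 1L
  }
  m <- m + 1L
  out_cls[m] <- cur_cls
  out_dur[m] <- cur_dur
  out_cls <- out_cls[seq_len(m)]
  out_dur <- out_dur[seq_len(m)]
  event_table(out_cls, out_dur, t0_ms = events$start_ms[1L],
              dead_time = dead_time,
              sampling_rate = attr(events, "sampling_rate"))
}
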