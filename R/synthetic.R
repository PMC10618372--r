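#' Trace acquisition configuration
#'
#' Parameters of the emulated cell-attached acquisition chain: 5 kHz
#' digitization after a 1 kHz 4-pole low-pass filter, Gaussian recording
#' noise, and a single effective driving potential (the cell's resting
#' potential minus the pipette potential, collapsed into one number because
#' the resting potential is not known in cell-attached mode).
#'
#' @param sampling_rate Digitization rate, Hz.
#' @param filter_cutoff Low-pass corner frequency, Hz; must be below half
#'   the sampling rate.
#' @param noise_sd Standard deviation of the recording noise as it appears
#'   in the digitized record, pA.
#' @param holding_potential Effective driving potential at the patch, mV.
#' @param duration Record duration, s.
#' @param n_channels_in_patch Number of identical channels under the
#'   pipette (superposition when > 1).
#' @param seed Integer seed controlling the noise.
#' @param oversample Internal oversampling factor used to realize the
#'   analogue filter on the piecewise-constant gating signal before
#'   decimation to `sampling_rate`.
#' @return A list of class `trace_config`.
#' @export
trace_config <- function(sampling_rate = 5000, filter_cutoff = 1000,
                         noise_sd = 0.3, holding_potential = -70,
                         duration = 10, n_channels_in_patch = 1L,
                         seed = 1L, oversample = 2L) {
  if (sampling_rate <= 2 * filter_cutoff) {
    stop("sampling theorem guard: sampling_rate must exceed 2 * filter_cutoff",
         call. = FALSE)
  }
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (n_channels_in_patch < 1L) stop("n_channels_in_patch must be >= 1", call. = FALSE)
  structure(list(sampling_rate = sampling_rate, filter_cutoff = filter_cutoff,
                 noise_sd = noise_sd, holding_potential = holding_potential,
                 duration = duration,
                 n_channels_in_patch = as.integer(n_channels_in_patch),
                 seed = as.integer(seed), oversample = as.integer(oversample)),
            class = "trace_config")
}

#' Sampled current trace
#'
#' @param samples Current samples, pA.
#' @param sampling_rate Hz.
#' @param metadata Named list (temperature, holding potential, seed, ...).
#' @return A list of class `current_trace`.
#' @export
current_trace <- function(samples, sampling_rate, metadata = list()) {
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop("trace contains non-finite samples", call. = FALSE)
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 metadata = metadata),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace: %d samples @ %g Hz (%.3g s)>\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  invisible(x)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Simulate single-channel gating as an exact Markov trajectory
#'
#' Draws a continuous-time trajectory of the scheme (exponential waiting
#' times, embedded-chain jumps), starting from a state drawn from the
#' equilibrium distribution, and collapses it to alternating open/closed
#' class dwells. Event times are exact (continuous); discretization only
#' happens at rendering.
#'
#' @param scheme A [kinetic_scheme()].
#' @param duration Trajectory duration in seconds.
#' @param seed Integer seed (reproducible trajectories).
#' @return An [event_table()] spanning at least `duration` seconds.
#' @export
simulate_gating <- function(scheme, duration, seed = 1L) {
  stopifnot(inherits(scheme, "kinetic_scheme"), duration > 0)
  duration_ms <- duration * 1000
  eq <- equilibrium(scheme)
  with_seed(seed, {
    start <- sample.int(n_states(scheme), 1L, prob = eq$occupancy)
    mean_dwell_state <- -1 / diag(scheme$Q)
    max_tr <- as.integer(min(2^31 - 1,
                             ceiling(duration_ms / min(mean_dwell_state)) * 3 + 1e4))
    path <- .ctmc_simulate(scheme$Q, start - 1L, duration_ms, max_tr)
    cls <- scheme$class_of_state[path$state]
    r <- rle(cls)
    dur <- as.numeric(tapply(path$dwell,
                             rep(seq_along(r$lengths), r$lengths), sum))
    event_table(r$values, dur)
  })
}

# Unitary open-channel current in pA at a driving potential (mV):
# i = g (V - Vrev), g in pS.
unitary_current <- function(scheme, holding_potential) {
  scheme$conductance * (holding_potential - scheme$vrev) / 1000
}

# 4-pole low-pass used as the acquisition anti-alias/analogue filter.
acq_filter <- function(fs, fc) {
  key <- sprintf("filt_%g_%g", fs, fc)
  cache_get_or(key, function() {
    filt <- signal::butter(4, fc / (fs / 2))
    h <- signal::filter(filt, c(1, numeric(8191)))
    list(filt = filt, noise_gain = sqrt(sum(h^2)))
  })
}

#' Render an idealized gating record as a noisy sampled current trace
#'
#' Builds the piecewise-constant pipette current (closed level 0 pA, open
#' level `g * (V - Vrev)`) on an oversampled grid, adds Gaussian noise,
#' applies the 4-pole low-pass acquisition filter, and decimates to the
#' digitization rate. Injected noise is scaled by the filter's noise gain
#' so that the rendered record's noise SD equals `config$noise_sd`. With
#' `n_channels_in_patch > 1`, supply a list of event tables (one per
#' channel); their currents superpose.
#'
#' @param events An [event_table()] (or list of them) spanning at least the
#'   configured duration.
#' @param scheme The generating [kinetic_scheme()] (conductance/reversal).
#' @param config A [trace_config()].
#' @return A [current_trace()]; `metadata$i_open` records the noiseless
#'   unitary open-level current (pA).
#' @export
render_trace <- function(events, scheme, config) {
  stopifnot(inherits(config, "trace_config"))
  if (inherits(events, "event_table")) events <- list(events)
  if (length(events) != config$n_channels_in_patch) {
    stop("parameter error: need one event table per channel in the patch",
         call. = FALSE)
  }
  duration_ms <- config$duration * 1000
  for (ev in events) {
    if (total_duration(ev) < duration_ms - 1e-6) {
      stop("events must span at least the configured duration", call. = FALSE)
    }
  }
  fs_ov <- config$sampling_rate * config$oversample
  n_ov <- round(config$duration * fs_ov)
  tgrid <- (seq_len(n_ov) - 0.5) / fs_ov * 1000  # sample midpoints, ms
  i_open <- unitary_current(scheme, config$holding_potential)
  sig <- numeric(n_ov)
  for (ev in events) {
    bounds <- c(ev$start_ms[1L], ev$start_ms + ev$duration_ms)
    lev <- ifelse(ev$class == "open", i_open, 0)
    sig <- sig + lev[pmin(pmax(findInterval(tgrid, bounds), 1L), nrow(ev))]
  }
  af <- acq_filter(fs_ov, config$filter_cutoff)
  x <- with_seed(config$seed, {
    if (config$noise_sd > 0) {
      sig + stats::rnorm(n_ov, 0, config$noise_sd / af$noise_gain)
    } else {
      sig
    }
  })
  # pad with the initial level so the causal filter starts settled
  npad <- 1024L
  x <- c(rep(x[1L], npad), x)
  y <- signal::filter(af$filt, x)[-seq_len(npad)]
  samples <- y[seq(1L, n_ov, by = config$oversample)]
  current_trace(samples, config$sampling_rate, metadata = list(
    temperature = scheme$reference_temperature,
    holding_potential = config$holding_potential,
    seed = config$seed, i_open = i_open, noise_sd = config$noise_sd,
    scheme_states = paste(scheme$states, collapse = ",")
  ))
}

#' Multi-temperature synthetic single-channel dataset
#'
#' One rendered cell-attached trace per temperature from the default
#' per-temperature Trpv4-like scheme, with a manifest recording the seeds
#' and the ground-truth dwell mixtures for parameter-recovery testing.
#'
#' @param temps Temperatures in degrees C (non-empty).
#' @param per_temp_duration Record duration per temperature, s.
#' @param seed Base seed; trace `i` uses `seed + i - 1`.
#' @param noise_sd,holding_potential Acquisition settings (see
#'   [trace_config()]).
#' @return A list with `traces` (named list of [current_trace()]),
#'   `events` (ground-truth [event_table()]s) and `manifest` (seeds plus
#'   ground-truth mixtures per temperature).
#' @export
make_temperature_dataset <- function(temps = c(37, 32, 22),
                                     per_temp_duration = 60, seed = 1L,
                                     noise_sd = 0.3,
                                     holding_potential = -70) {
  if (length(temps) == 0L) stop("parameter error: empty temperature list", call. = FALSE)
  if (per_temp_duration <= 0) stop("parameter error: duration must be > 0", call. = FALSE)
  traces <- list()
  events <- list()
  manifest <- list()
  for (i in seq_along(temps)) {
    tt <- temps[i]
    sch <- trpv4_scheme(tt)
    si <- as.integer(seed + i - 1L)
    ev <- simulate_gating(sch, per_temp_duration, seed = si)
    cfg <- trace_config(noise_sd = noise_sd,
                        holding_potential = holding_potential,
                        duration = per_temp_duration, seed = si + 1000L)
    key <- as.character(tt)
    traces[[key]] <- render_trace(ev, sch, cfg)
    events[[key]] <- ev
    manifest[[key]] <- list(
      temperature = tt, seed_gating = si, seed_noise = si + 1000L,
      closed_mixture = dwell_pdf(sch, "closed"),
      open_mixture = dwell_pdf(sch, "open")
    )
  }
  list(traces = traces, events = events, manifest = manifest)
}

#' Synthetic spontaneous action-current trace
#'
#' Embeds a stereotyped biphasic action-current waveform at homogeneous
#' Poisson times in Gaussian noise, returning the ground-truth event times
#' for validating the adaptive-threshold detector.
#'
#' @param rate Mean firing rate, Hz (>= 0).
#' @param duration Record duration, s.
#' @param noise_sd Noise SD, pA.
#' @param amplitude Peak (downward) amplitude of the waveform, pA.
#' @param seed Integer seed.
#' @param sampling_rate Hz.
#' @return A list with `trace` (a [current_trace()]) and `spike_times_ms`.
#' @export
make_spike_trace <- function(rate, duration, noise_sd = 1, amplitude = 25,
                             seed = 1L, sampling_rate = 5000) {
  if (rate < 0) stop("parameter error: rate must be >= 0", call. = FALSE)
  if (duration <= 0) stop("parameter error: duration must be > 0", call. = FALSE)
  n <- round(duration * sampling_rate)
  dt_ms <- 1000 / sampling_rate
  # biphasic waveform: sharp downward deflection with an upward rebound
  wt <- seq(0, 4, by = dt_ms)  # ms
  w <- -amplitude * exp(-((wt - 0.8) / 0.35)^2) +
    0.45 * amplitude * exp(-((wt - 1.9) / 0.6)^2)
  with_seed(seed, {
    nspk <- stats::rpois(1L, rate * duration)
    spike_times_ms <- sort(stats::runif(nspk, 0, duration * 1000))
    x <- stats::rnorm(n, 0, noise_sd)
    idx0 <- round(spike_times_ms / dt_ms)
    for (s in idx0) {
      ii <- s + seq_along(w)
      keep <- ii >= 1L & ii <= n
      x[ii[keep]] <- x[ii[keep]] + w[keep]
    }
    list(trace = current_trace(x, sampling_rate,
                               metadata = list(rate = rate, seed = seed,
                                               amplitude = amplitude,
                                               noise_sd = noise_sd)),
         spike_times_ms = spike_times_ms)
  })
}
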