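#' Closed dwell-time recovery experiment
#'
#' Runs the full single-channel analysis pipeline on synthetic data at one
#' temperature: build the default Trpv4-like scheme, simulate gating long
#' enough to yield the requested number of closed dwells, render noisy
#' cell-attached traces, idealize by segmental k-means, impose the dead
#' time, and ML-fit a 3-component closed dwell mixture. Long records are
#' processed in chunks (each chunk idealized independently; censored
#' boundary dwells of each chunk are excluded from fitting).
#'
#' @param temperature Temperature in degrees C (22, 32 or 37 for the
#'   tabulated schemes).
#' @param n_closed_target Closed dwells to accumulate (after dead-time
#'   imposition) before fitting.
#' @param seed Integer seed for gating and noise.
#' @param dead_time Dead time in ms.
#' @param noise_sd Trace noise SD, pA.
#' @param holding_potential Driving potential, mV.
#' @param chunk_s Chunk length in seconds for rendering/idealization.
#' @param max_chunks Safety cap on the number of chunks.
#' @return A list: `fit` (the closed `mixture_fit`), `truth` (the
#'   generator's analytic closed mixture), `po` (idealized record Po),
#'   `po_analytic`, `n_closed`, `duration_s`.
#' @export
dwell_recovery_experiment <- function(temperature = 22,
                                      n_closed_target = 50000,
                                      seed = 1L, dead_time = 0.3,
                                      noise_sd = 0.3,
                                      holding_potential = -70,
                                      chunk_s = 120, max_chunks = 60L) {
  sch <- trpv4_scheme(temperature)
  truth <- dwell_pdf(sch, "closed")
  eq <- equilibrium(sch)
  # expected record length needed, plus margin
  cycle_ms <- eq$mean_open + eq$mean_closed
  need_s <- n_closed_target * cycle_ms / 1000 * 1.1
  closed <- numeric(0)
  open_ms <- 0
  total_ms <- 0
  chunk <- 0L
  while (length(closed) < n_closed_target && chunk < max_chunks) {
    chunk <- chunk + 1L
    if (chunk > 1L && length(closed) == 0L) break
    dur <- min(chunk_s, max(need_s - (chunk - 1L) * chunk_s, chunk_s / 4))
    ev <- simulate_gating(sch, dur, seed = seed + 17L * chunk)
    cfg <- trace_config(duration = dur, noise_sd = noise_sd,
                        holding_potential = holding_potential,
                        seed = seed + 17L * chunk + 1L)
    tr <- render_trace(ev, sch, cfg)
    am <- fit_amplitude_model(tr)
    if (!am$open_detected) next
    id <- apply_dead_time(skm_idealize(tr, am), dead_time)
    closed <- c(closed, dwells_of_class(id, "closed"))
    open_ms <- open_ms + sum(id$duration_ms[id$class == "open"])
    total_ms <- total_ms + total_duration(id)
  }
  if (length(closed) < 100L) {
    stop("recovery experiment produced too few closed dwells", call. = FALSE)
  }
  fit <- fit_mixture(closed, 3L, dead_time = dead_time, class = "closed",
                     seed = seed)
  list(fit = fit, truth = truth, po = open_ms / total_ms,
       po_analytic = eq$po, n_closed = length(closed),
       duration_s = total_ms / 1000)
}

#' Current-voltage (IV) recovery experiment
#'
#' Generates cell-attached traces at several driving potentials from the
#' default Trpv4-like channel, fits a two-Gaussian amplitude model to each
#' all-points histogram, and linearly regresses the unitary open-channel
#' amplitude on potential. The slope estimates the unitary conductance
#' (pS) and the zero-current intercept the reversal potential (mV).
#'
#' @param potentials Driving potentials, mV.
#' @param duration Trace duration per potential, s.
#' @param temperature Temperature of the generating scheme, degrees C.
#' @param noise_sd Trace noise SD, pA. The default keeps SNR >= 8 at the
#'   weakest driving potential of the default set (unitary current 0.53 pA
#'   at -10 mV).
#' @param seed Integer seed.
#' @return A list: `conductance_pS`, `vrev_mV`, `amplitudes` (per-potential
#'   fitted unitary currents, pA), `potentials`, `fit` (the `lm` object).
#' @export
iv_experiment <- function(potentials = c(-70, -50, -30, -10, 10),
                          duration = 60, temperature = 22,
                          noise_sd = 0.065, seed = 1L) {
  sch <- trpv4_scheme(temperature)
  amps <- numeric(length(potentials))
  for (i in seq_along(potentials)) {
    ev <- simulate_gating(sch, duration, seed = seed + 101L * i)
    cfg <- trace_config(duration = duration, noise_sd = noise_sd,
                        holding_potential = potentials[i],
                        seed = seed + 101L * i + 1L)
    tr <- render_trace(ev, sch, cfg)
    am <- fit_amplitude_model(tr)
    if (!am$open_detected) {
      stop(sprintf("no openings resolved at %g mV", potentials[i]), call. = FALSE)
    }
    amps[i] <- am$open_level - am$closed_level
  }
  fit <- stats::lm(amps ~ potentials)
  slope <- stats::coef(fit)[["potentials"]]   # pA/mV
  intercept <- stats::coef(fit)[["(Intercept)"]]
  list(conductance_pS = slope * 1000, vrev_mV = -intercept / slope,
       amplitudes = amps, potentials = potentials, fit = fit)
}
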