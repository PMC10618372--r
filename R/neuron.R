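#' Configuration of the stochastic PVN neurone model
#'
#' Assembles the full parameterisation of the single-compartment model:
#' deterministic Hodgkin-Huxley spike machinery, stochastic channel
#' populations (delayed-rectifier Kv, thermosensitive Trpv4-like and
#' Trpm2-like TRP channels, Ca2+-activated SK channels of the
#' Moczydlowski-Latorre type), a TRP-SK Ca2+ microdomain exchanging with
#' the bulk cytosol, and Poisson synaptic drive (direct excitation plus an
#' excitatory-driven inhibitory interneurone). Temperature acts only
#' through the TRP schemes: the Trpv4-like scheme is the measured
#' per-temperature scheme ([trpv4_scheme()]), the Trpm2-like channel
#' scales its opening rate with Q10 = 15.6; every other element is
#' temperature-insensitive by construction.
#'
#' Default magnitudes (channel counts, microdomain constants, drive rates)
#' are package calibration constants frozen so that the no-drug model
#' fires sparsely (< 1 Hz) at 37 degrees C and several-fold faster at 22
#' degrees C; see the methods vignette.
#'
#' @param temperature Bath temperature, degrees C.
#' @param n_trpv4,n_trpm2,n_sk,n_kv Channel counts.
#' @param drug_block Named list of block fractions in `[0, 1]` per channel
#'   population (`trpv4`, `trpm2`, `sk`, `kv`).
#' @param rate_e Mean rate of direct excitatory Poisson drive, Hz.
#' @param rate_inh_drive Mean rate of the excitatory train driving the
#'   inhibitory interneurone, Hz.
#' @param jitter_sd SD of the per-run lognormal jitter applied to the two
#'   drive rates (run-to-run variability of the synaptic bombardment).
#' @param trpm2_open_rate_37,trpm2_close_rate Base rates (1/ms) of the
#'   two-state Trpm2-like channel at 37 degrees C; the opening (forward)
#'   rate carries the Q10.
#' @param trpm2_q10 Q10 of the Trpm2-like opening rate.
#' @param ... Advanced overrides of the remaining biophysical constants
#'   (see the function source for the full list and units).
#' @return A list of class `neuron_config`.
#' @export
neuron_config <- function(temperature = 37,
                          n_trpv4 = 3L, n_trpm2 = 200L, n_sk = 1500L,
                          n_kv = 100L,
                          drug_block = list(),
                          rate_e = 40, rate_inh_drive = 60,
                          jitter_sd = 0.08,
                          trpm2_open_rate_37 = 0.06,
                          trpm2_close_rate = 0.14,
                          trpm2_q10 = 15.6,
                          ...) {
  base <- list(
    temperature = temperature,
    # membrane & spike machinery
    capacitance = 15, g_leak = 4.5, e_leak = -54.4,
    g_na = 1800, e_na = 50, g_k = 540, e_k = -77,
    # stochastic populations
    n_kv = as.integer(n_kv), gamma_kv = 0.010,
    n_trpv4 = as.integer(n_trpv4), gamma_trpv4 = 0.0597,
    e_trpv4 = -18.89, pca_trpv4 = 6,
    n_trpm2 = as.integer(n_trpm2), gamma_trpm2 = 0.025,
    e_trpm2 = 0, pca_trpm2 = 0.7,
    trpm2_open_rate_37 = trpm2_open_rate_37,
    trpm2_close_rate = trpm2_close_rate, trpm2_q10 = trpm2_q10,
    n_sk = as.integer(n_sk), gamma_sk = 0.010,
    sk_abar = 0.48, sk_bbar = 0.45,
    sk_k1 = 0.03, sk_d1 = 0, sk_k2 = 0.0025, sk_d2 = 0,
    # microdomain (two-compartment buffered exchange)
    vol_md = 3e-16, buffer_capacity = 15, k_md = 1,
    vol_ratio = 1e-5, tau_bulk = 200, ca_rest = 0.05,
    # synaptic drive
    rate_e = rate_e, w_e = 0.8, tau_e = 3,
    rate_inh_drive = rate_inh_drive, inh_gain = 30, inh_theta = 1.2,
    w_i = 1.5, tau_i = 10, e_i = -75, tau_s = 20,
    jitter_sd = jitter_sd,
    # integration / detection
    dt = 0.025, channel_every = 4L, record_every = 40L,
    spike_threshold = -20, refractory = 3, v_init = -65,
    drug_block = list(trpv4 = 0, trpm2 = 0, sk = 0, kv = 0)
  )
  for (nm in names(drug_block)) {
    if (!nm %in% names(base$drug_block)) {
      stop("unknown channel in drug_block: ", nm, call. = FALSE)
    }
    f <- drug_block[[nm]]
    if (f < 0 || f > 1) stop("parameter error: block fraction must be in [0,1]", call. = FALSE)
    base$drug_block[[nm]] <- f
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(base))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "), call. = FALSE)
  base[names(dots)] <- dots
  if (base$capacitance <= 0) stop("capacitance must be > 0", call. = FALSE)
  if (any(c(base$n_trpv4, base$n_trpm2, base$n_sk, base$n_kv) < 0)) {
    stop("channel counts must be >= 0", call. = FALSE)
  }
  structure(base, class = "neuron_config")
}

#' @export
print.neuron_config <- function(x, ...) {
  cat(sprintf(
    "<neuron_config: %g C; Trpv4 %d, Trpm2 %d, SK %d, Kv %d; block trpv4 %g trpm2 %g>\n",
    x$temperature, x$n_trpv4, x$n_trpm2, x$n_sk, x$n_kv,
    x$drug_block$trpv4, x$drug_block$trpm2))
  invisible(x)
}

#' Pharmacological block of channel populations
#'
#' Returns a configuration with the effective count of the targeted
#' channel populations scaled down by the block fraction. Gadolinium
#' blocks the warm-activated Trpv4-like (and any Trpv3-like, which the
#' default model does not instantiate) population; it is treated as NOT
#' blocking the Trpm2-like channel. Econazole blocks the Trpm2-like
#' population.
#'
#' @param config A [neuron_config()].
#' @param drug `"gadolinium"` or `"econazole"`.
#' @param fraction Block fraction in `[0, 1]` (default 1, full block).
#' @return A new `neuron_config`.
#' @export
apply_drug <- function(config, drug = c("gadolinium", "econazole"),
                       fraction = 1) {
  stopifnot(inherits(config, "neuron_config"))
  drug <- match.arg(drug)
  if (fraction < 0 || fraction > 1) {
    stop("parameter error: block fraction must be in [0, 1]", call. = FALSE)
  }
  if (drug == "gadolinium") {
    config$drug_block$trpv4 <- fraction
  } else {
    config$drug_block$trpm2 <- fraction
  }
  config
}

trpm2_scheme_matrices <- function(config) {
  k_open <- config$trpm2_open_rate_37 *
    config$trpm2_q10^((config$temperature - 37) / 10)
  k_close <- config$trpm2_close_rate
  Q <- matrix(c(-k_open, k_open, k_close, -k_close), 2, 2, byrow = TRUE)
  list(Q = Q, open = c(FALSE, TRUE),
       po = k_open / (k_open + k_close))
}

eff_count <- function(n, block) max(0L, as.integer(round(n * (1 - block))))

#' Run the stochastic PVN neurone model
#'
#' Integrates the membrane equation with stochastic channel-population
#' updates for `duration` seconds at the configured temperature and
#' returns the voltage/Ca2+ trajectories (1-ms resolution) and spike
#' times. Spikes are threshold crossings of the membrane potential (the
#' model's action-current observable); population channel counts are
#' conserved exactly at every step.
#'
#' @param config A [neuron_config()].
#' @param duration Simulated time, s.
#' @param seed Integer seed (full trajectory reproducibility).
#' @return A list of class `sim_result`: `spike_times_ms`, `acf_hz`,
#'   `t_ms`, `v`, `ca_md`, `ca_bulk`, `open_*` traces, `temperature`,
#'   `seed`, `aborted`.
#' @export
run_neuron <- function(config, duration = 60, seed = 1L) {
  stopifnot(inherits(config, "neuron_config"), duration > 0)
  v4 <- trpv4_scheme(config$temperature)
  m2 <- trpm2_scheme_matrices(config)
  n_v4 <- eff_count(config$n_trpv4, config$drug_block$trpv4)
  n_m2 <- eff_count(config$n_trpm2, config$drug_block$trpm2)
  n_sk <- eff_count(config$n_sk, config$drug_block$sk)
  n_kv <- eff_count(config$n_kv, config$drug_block$kv)
  eqv4 <- equilibrium(v4)$occupancy
  res <- with_seed(seed, {
    init_v4 <- if (n_v4 > 0) {
      as.integer(stats::rmultinom(1, n_v4, eqv4))
    } else {
      integer(length(eqv4))
    }
    init_m2 <- if (n_m2 > 0) {
      as.integer(stats::rmultinom(1, n_m2, c(1 - m2$po, m2$po)))
    } else {
      c(0L, 0L)
    }
    jit <- exp(stats::rnorm(2, 0, config$jitter_sd))
    par <- list(
      dt = config$dt, n_steps = as.integer(round(duration * 1000 / config$dt)),
      channel_every = config$channel_every,
      record_every = config$record_every,
      capacitance = config$capacitance, g_leak = config$g_leak,
      e_leak = config$e_leak, g_na = config$g_na, e_na = config$e_na,
      g_k = config$g_k, e_k = config$e_k,
      n_kv = n_kv, gamma_kv = config$gamma_kv,
      q_trpv4 = v4$Q, open_trpv4 = v4$class_of_state == "open",
      n_trpv4 = n_v4, gamma_trpv4 = config$gamma_trpv4,
      e_trpv4 = config$e_trpv4, pca_trpv4 = config$pca_trpv4,
      init_trpv4 = init_v4,
      q_trpm2 = m2$Q, open_trpm2 = m2$open, n_trpm2 = n_m2,
      gamma_trpm2 = config$gamma_trpm2, e_trpm2 = config$e_trpm2,
      pca_trpm2 = config$pca_trpm2, init_trpm2 = init_m2,
      n_sk = n_sk, gamma_sk = config$gamma_sk,
      sk_abar = config$sk_abar, sk_bbar = config$sk_bbar,
      sk_k1 = config$sk_k1, sk_d1 = config$sk_d1,
      sk_k2 = config$sk_k2, sk_d2 = config$sk_d2,
      ca_per_pA = 5.182e-15 / config$vol_md,
      buffer_div = 1 + config$buffer_capacity,
      k_md = config$k_md, vol_ratio = config$vol_ratio,
      tau_bulk = config$tau_bulk, ca_rest = config$ca_rest,
      rate_e = config$rate_e * jit[1L], w_e = config$w_e,
      tau_e = config$tau_e,
      rate_inh_drive = config$rate_inh_drive * jit[2L],
      inh_gain = config$inh_gain, inh_theta = config$inh_theta,
      w_i = config$w_i, tau_i = config$tau_i, e_i = config$e_i,
      tau_s = config$tau_s,
      spike_threshold = config$spike_threshold,
      refractory = config$refractory, v_init = config$v_init
    )
    .neuron_sim(par)
  })
  if (isTRUE(res$aborted)) {
    stop("unstable integration: |V| exceeded 200 mV", call. = FALSE)
  }
  res$acf_hz <- length(res$spike_times_ms) / duration
  res$temperature <- config$temperature
  res$seed <- seed
  class(res) <- "sim_result"
  res
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result: %g C, %.4g s, %d spikes (ACf %.3g Hz)>\n",
              x$temperature, max(x$t_ms) / 1000, length(x$spike_times_ms),
              x$acf_hz))
  invisible(x)
}

#' Temperature sweep of the stochastic neurone model
#'
#' Runs the model at each temperature with `n_runs` independent seeds
#' (seeds are paired across temperatures: run r uses the same seed at
#' every temperature, so temperature contrasts are paired) and returns the
#' action-current frequency of every run as a tidy table.
#'
#' @param config A [neuron_config()] (its `temperature` field is
#'   overridden).
#' @param temps Temperatures in degrees C.
#' @param n_runs Independent runs per temperature.
#' @param duration Simulated seconds per run.
#' @param seed Base seed; run r uses `seed + r - 1`.
#' @param drug_label Label stored in the `drug` column.
#' @return A data.frame of class `sweep_result`: `temperature_C`, `drug`,
#'   `run`, `seed`, `acf_hz`.
#' @export
temperature_sweep <- function(config, temps = c(37, 32, 27, 22),
                              n_runs = 5L, duration = 60, seed = 1L,
                              drug_label = "none") {
  stopifnot(inherits(config, "neuron_config"))
  if (length(temps) == 0L || any(!is.finite(temps))) {
    stop("parameter error: invalid temperature list", call. = FALSE)
  }
  rows <- list()
  for (tt in temps) {
    cfg <- config
    cfg$temperature <- tt
    for (r in seq_len(n_runs)) {
      s <- as.integer(seed + r - 1L)
      res <- run_neuron(cfg, duration = duration, seed = s)
      rows[[length(rows) + 1L]] <- data.frame(
        temperature_C = tt, drug = drug_label, run = r, seed = s,
        acf_hz = res$acf_hz)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Adaptive-threshold action-current detection
#'
#' Detects action currents in a (pipette) current trace with a running
#' median baseline and a robust noise scale: samples deflecting beyond
#' `k` times the MAD of the baseline residual trigger an event, with a
#' refractory lockout; the event time is the extremum of the deflection.
#' Detection is invariant to any constant offset of the trace by
#' construction.
#'
#' @param trace A [current_trace()].
#' @param k Threshold in robust-SD units.
#' @param refractory_ms Lockout after each event, ms.
#' @param baseline_ms Running-median window, ms.
#' @param polarity `-1` for downward events (default), `+1` for upward.
#' @return Numeric vector of event times, ms.
#' @export
detect_action_currents <- function(trace, k = 6, refractory_ms = 5,
                                   baseline_ms = 200, polarity = -1) {
  stopifnot(inherits(trace, "current_trace"))
  x <- trace$samples
  n <- length(x)
  if (n < 10L) return(numeric(0))
  dt_ms <- 1000 / trace$sampling_rate
  win <- max(3L, round(baseline_ms / dt_ms))
  if (win %% 2L == 0L) win <- win + 1L
  win <- min(win, if (n %% 2L == 1L) n else n - 1L)
  base <- stats::runmed(x, win)
  resid <- polarity * (x - base)
  sigma <- stats::mad(resid)
  if (sigma <= 0) sigma <- stats::sd(resid)
  if (!is.finite(sigma) || sigma <= 0) return(numeric(0))
  thr <- k * sigma
  above <- resid > thr
  if (!any(above)) return(numeric(0))
  refrac_n <- max(1L, round(refractory_ms / dt_ms))
  times <- numeric(0)
  i <- 1L
  while (i <= n) {
    if (above[i]) {
      j_end <- min(i + refrac_n, n)
      seg <- i:j_end
      peak <- seg[which.max(resid[seg])]
      times <- c(times, (peak - 1L) * dt_ms)
      i <- peak + refrac_n
    } else {
      i <- i + 1L
    }
  }
  times
}
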