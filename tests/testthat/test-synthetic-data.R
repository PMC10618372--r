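test_that("trace_config enforces the sampling theorem and basic bounds", {
  expect_error(trace_config(sampling_rate = 1500, filter_cutoff = 1000),
               "sampling theorem")
  expect_error(trace_config(duration = 0), "duration")
  expect_error(trace_config(noise_sd = -1), "noise_sd")
})

test_that("simulate_gating is seed-deterministic and alternates classes", {
  sch <- trpv4_scheme(22)
  a <- simulate_gating(sch, 5, seed = 7)
  b <- simulate_gating(sch, 5, seed = 7)
  c <- simulate_gating(sch, 5, seed = 8)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$duration_ms, c$duration_ms)))
  expect_true(all(a$class[-1L] != a$class[-nrow(a)]))
})

test_that("simulated dwell means match the exponential expectation", {
  sch <- two_state_scheme(1, 1)   # both mean dwells 1 ms
  ev <- simulate_gating(sch, 25, seed = 2)   # ~ 1e4+ dwells per class
  for (cls in c("open", "closed")) {
    d <- dwells_of_class(ev, cls)
    expect_gt(length(d), 5e3)
    se <- sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d) - 1), 3 * se)
  }
})

test_that("long-run open fraction matches analytic Po", {
  sch <- trpv4_scheme(37)
  ev <- simulate_gating(sch, 300, seed = 21)
  po_mc <- sum(ev$duration_ms[ev$class == "open"]) / total_duration(ev)
  expect_lt(abs(po_mc - equilibrium(sch)$po) / equilibrium(sch)$po, 0.05)
})

test_that("rendering reproduces the ohmic unitary current", {
  # single dwell spanning the record: noiseless level g (V - Vrev)
  sch <- two_state_scheme(1, 1, conductance = 59.7, vrev = -18.89)
  ev <- event_table("open", 1500)
  cfg <- trace_config(noise_sd = 0, holding_potential = -118.89,
                      duration = 1, seed = 1)
  tr <- render_trace(ev, sch, cfg)
  expect_equal(tr$metadata$i_open, -5.97)
  expect_lt(max(abs(tr$samples - (-5.97))), 1e-6)
  # at the reversal potential the open level vanishes
  cfg0 <- trace_config(noise_sd = 0, holding_potential = -18.89,
                       duration = 1, seed = 1)
  tr0 <- render_trace(ev, sch, cfg0)
  expect_lt(max(abs(tr0$samples)), 1e-9)
})

test_that("rendered noise SD matches the configured value", {
  sch <- two_state_scheme(1e-4, 10)  # essentially always closed
  ev <- simulate_gating(sch, 4, seed = 3)
  cfg <- trace_config(noise_sd = 0.3, duration = 4, seed = 4)
  tr <- render_trace(ev, sch, cfg)
  expect_lt(abs(sd(tr$samples) - 0.3) / 0.3, 0.05)
})

test_that("amplitude histogram of a rendered trace is bimodal at the unitary current", {
  sch <- trpv4_scheme(22)
  ev <- simulate_gating(sch, 60, seed = 5)
  cfg <- trace_config(noise_sd = 0.25, holding_potential = -70,
                      duration = 60, seed = 6)
  tr <- render_trace(ev, sch, cfg)
  am <- fit_amplitude_model(tr)
  expect_true(am$open_detected)
  expect_lt(abs((am$open_level - am$closed_level) - tr$metadata$i_open) /
              abs(tr$metadata$i_open), 0.03)
})

test_that("temperature datasets carry the tabulated ground truth", {
  ds <- make_temperature_dataset(c(37, 22), per_temp_duration = 3, seed = 1)
  expect_named(ds$traces, c("37", "22"))
  gt22 <- ds$manifest[["22"]]$closed_mixture
  expect_equal(gt22$taus, c(0.58, 5.26, 71.22), tolerance = 1e-4)
  expect_error(make_temperature_dataset(numeric(0)), "empty temperature")
  expect_error(make_temperature_dataset(22, per_temp_duration = 0), "duration")
  # different seeds: different sample paths, identical ground truth
  ds2 <- make_temperature_dataset(c(37, 22), per_temp_duration = 3, seed = 99)
  expect_false(identical(ds$traces[["22"]]$samples, ds2$traces[["22"]]$samples))
  expect_equal(ds2$manifest[["22"]]$closed_mixture$taus, gt22$taus)
})

test_that("spike traces honour the Poisson rate and the zero-rate edge", {
  z <- make_spike_trace(0, 10, seed = 1)
  expect_length(z$spike_times_ms, 0)
  s <- make_spike_trace(1, 100, seed = 2)
  expect_lt(abs(length(s$spike_times_ms) - 100), 3 * sqrt(100))
  expect_error(make_spike_trace(-1, 10), "rate")
  # noiseless waveform train is recovered perfectly by the detector
  q <- make_spike_trace(2, 30, noise_sd = 1e-4, seed = 3)
  det <- detect_action_currents(q$trace)
  expect_equal(length(det), length(q$spike_times_ms))
})
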