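passive_config <- function(...) {
  neuron_config(n_trpv4 = 0L, n_trpm2 = 0L, n_sk = 0L, n_kv = 0L,
                g_na = 0, g_k = 0, rate_e = 0, rate_inh_drive = 0,
                e_leak = -60, ...)
}

test_that("a passive membrane rests at the leak reversal", {
  r <- run_neuron(passive_config(), duration = 0.5, seed = 1)
  expect_lt(abs(r$v[length(r$v)] - (-60)), 0.01)
  expect_length(r$spike_times_ms, 0)
})

test_that("simulation results are seed-deterministic", {
  cfg <- neuron_config(temperature = 27)
  a <- run_neuron(cfg, duration = 2, seed = 5)
  b <- run_neuron(cfg, duration = 2, seed = 5)
  expect_identical(a$v, b$v)
  expect_identical(a$spike_times_ms, b$spike_times_ms)
  c <- run_neuron(cfg, duration = 2, seed = 6)
  expect_false(identical(a$v, c$v))
})

test_that("open channel counts stay within population bounds", {
  cfg <- neuron_config(temperature = 32)
  r <- run_neuron(cfg, duration = 5, seed = 2)
  expect_true(all(r$open_trpv4 >= 0 & r$open_trpv4 <= cfg$n_trpv4))
  expect_true(all(r$open_trpm2 >= 0 & r$open_trpm2 <= cfg$n_trpm2))
  expect_true(all(r$open_sk >= 0 & r$open_sk <= cfg$n_sk))
  expect_true(all(diff(r$spike_times_ms) > 0))
})

test_that("microdomain and bulk calcium respect the nanodomain premise", {
  r <- run_neuron(neuron_config(temperature = 37), duration = 20, seed = 3)
  expect_true(all(r$ca_md > 0))
  expect_true(all(r$ca_bulk > 0))
  # microdomain transients are large while bulk calcium stays near rest
  expect_gt(max(r$ca_md), 10 * max(r$ca_bulk))
  expect_lt(max(r$ca_bulk), 2 * 0.05 + 0.05)  # < 2x resting (plus rest)
  expect_gt(mean(r$ca_md), mean(r$ca_bulk))
})

test_that("temperature acts only through the thermosensitive channels", {
  cfg <- neuron_config(n_trpv4 = 0L, n_trpm2 = 0L)
  a <- vapply(1:3, function(s) {
    cfg$temperature <- 37
    run_neuron(cfg, 20, seed = s)$acf_hz
  }, numeric(1))
  b <- vapply(1:3, function(s) {
    cfg$temperature <- 22
    run_neuron(cfg, 20, seed = s)$acf_hz
  }, numeric(1))
  expect_identical(a, b)   # identical seeds, no thermosensitive element
})

test_that("drug application scales the targeted population only", {
  cfg <- neuron_config()
  same <- apply_drug(cfg, "gadolinium", 0)
  expect_identical(unclass(same), unclass(cfg))
  gd <- apply_drug(cfg, "gadolinium", 1)
  expect_equal(gd$drug_block$trpv4, 1)
  expect_equal(gd$drug_block$trpm2, 0)
  ec <- apply_drug(cfg, "econazole", 0.5)
  expect_equal(ec$drug_block$trpm2, 0.5)
  expect_error(apply_drug(cfg, "econazole", 1.5), "\\[0, 1\\]")
  expect_error(neuron_config(drug_block = list(nmda = 1)), "unknown channel")
})

test_that("raising the Trpv4 count lowers firing at 37 C", {
  # probed at elevated drive so the 37 C rate has dynamic range
  base <- neuron_config(rate_e = 90)
  more <- neuron_config(n_trpv4 = 9L, rate_e = 90)
  d <- vapply(1:5, function(s) {
    run_neuron(base, 20, seed = s)$acf_hz -
      run_neuron(more, 20, seed = s)$acf_hz
  }, numeric(1))
  expect_gt(mean(d), 0)
  expect_gte(mean(d >= 0), 0.8)
})

test_that("the action-current detector is accurate and offset-invariant", {
  s <- make_spike_trace(2, 60, noise_sd = 1.5, amplitude = 25, seed = 4)
  det <- detect_action_currents(s$trace)
  # recall >= 99% with <= 1 false positive per minute at SNR ~ 17
  matched <- vapply(s$spike_times_ms, function(t0) {
    any(abs(det - t0) < 5)
  }, logical(1))
  expect_gte(mean(matched), 0.99)
  expect_lte(length(det) - sum(matched), 1)
  # pure noise: no events at the default threshold
  noise <- current_trace(rnorm(5000 * 30, 0, 1.5), 5000)
  expect_lte(length(detect_action_currents(noise)), 1)
  # constant offsets do not matter
  shifted <- current_trace(s$trace$samples + 40, 5000)
  expect_equal(detect_action_currents(shifted), det)
})

test_that("temperature sweeps return tidy per-run results", {
  sw <- temperature_sweep(neuron_config(), temps = c(37, 22), n_runs = 2L,
                          duration = 5, seed = 1)
  expect_s3_class(sw, "sweep_result")
  expect_equal(nrow(sw), 4L)
  expect_named(sw, c("temperature_C", "drug", "run", "seed", "acf_hz"))
  expect_true(all(sw$acf_hz >= 0))
  expect_error(temperature_sweep(neuron_config(), temps = numeric(0)),
               "temperature")
})
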