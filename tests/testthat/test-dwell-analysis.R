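test_that("log binning conserves counts and locates the transform peak", {
  set.seed(71)
  d <- rexp(20000, rate = 1)   # tau = 1 ms
  h <- log_bin(d, bins_per_decade = 10)
  expect_equal(sum(h$counts), length(d))
  # square-root-ordinate peak sits at the time constant
  peak <- h$mids[which.max(sqrt(h$counts))]
  expect_gt(peak, 10^-0.25)
  expect_lt(peak, 10^0.25)
  # all-equal dwells fall in one bin
  h1 <- log_bin(rep(2.5, 40))
  expect_equal(sum(h1$counts > 0), 1L)
  expect_error(log_bin(numeric(0)), "no dwells")
  # conservation over random inputs
  for (i in 1:20) {
    d <- rlnorm(sample(10:2000, 1), 0, 1.5)
    expect_equal(sum(log_bin(d)$counts), length(d))
  }
})

test_that("single-component truncated fit equals the closed-form MLE", {
  set.seed(72)
  td <- 0.3
  d <- td + rexp(5000, rate = 1 / 2)   # truncated exponential, tau = 2
  f <- fit_mixture(d, 1L, dead_time = td)
  expect_equal(f$mixture$taus, mean(d) - td, tolerance = 1e-12)
  expect_equal(f$n_components, 1L)
  expect_error(fit_mixture(c(0.1, 0.5), 1L, dead_time = 0.3), "dead_time")
})

test_that("three-component ML fit recovers the tabulated 22 C closed mixture", {
  set.seed(73)
  mix <- trpv4_closed_mixtures()[["22"]]
  td <- 0.3
  d <- rmixexp(9e4, mix)
  d <- d[d >= td][1:50000]
  f <- fit_mixture(d, 3L, dead_time = td)
  expect_lt(max(abs(f$mixture$taus - mix$taus) / mix$taus), 0.15)
  expect_lt(max(abs(f$mixture$areas - mix$areas)), 0.10)
  # likelihood is monotone non-decreasing in the number of components
  lls <- vapply(1:3, function(k) fit_mixture(d, k, dead_time = td)$loglik,
                numeric(1))
  expect_true(all(diff(lls) >= -1e-6))
})

test_that("refitting data simulated from a fitted mixture is self-consistent", {
  set.seed(74)
  mix <- dwell_mixture("closed", c(0.5, 8), c(0.6, 0.4))
  d <- rmixexp(20000, mix)
  f1 <- fit_mixture(d, 2L)
  d2 <- rmixexp(20000, f1$mixture)
  f2 <- fit_mixture(d2, 2L)
  # per-dwell log-likelihood agrees within Monte-Carlo error
  expect_lt(abs(f1$loglik / f1$n - f2$loglik / f2$n), 0.03)
  expect_lt(max(abs(log(f2$mixture$taus / f1$mixture$taus))), 0.15)
})

test_that("likelihood-ratio selection is calibrated and powered", {
  # single-exponential data: nearly always selects one component
  picks1 <- vapply(1:20, function(s) {
    set.seed(800 + s)
    select_components(rexp(10000, 1 / 3), max_n = 3, seed = s)$n_components
  }, integer(1))
  expect_gte(mean(picks1 == 1L), 0.9)
  # well-separated three-component data: selects three
  mix3 <- dwell_mixture("closed", c(0.5, 5, 70), c(0.5, 0.3, 0.2))
  set.seed(75)
  pick3 <- select_components(rmixexp(50000, mix3), max_n = 3, seed = 1)
  expect_equal(pick3$n_components, 3L)
  # tiny samples never support three components
  set.seed(76)
  picks_tiny <- vapply(1:10, function(s) {
    select_components(rmixexp(10, mix3), max_n = 3, seed = s)$n_components
  }, integer(1))
  expect_true(all(picks_tiny < 3L))
})

test_that("po_and_means summarises idealized records", {
  ev <- event_table(rep(c("open", "closed"), 10), rep(2, 20))
  pm <- po_and_means(ev)
  expect_equal(pm$po, 0.5)
  expect_equal(pm$mean_open, 2)
  one <- event_table("open", 100)
  expect_equal(po_and_means(one)$po, 1)
  expect_error(po_and_means(event_table(character(0), numeric(0))), "empty")
  # long simulated record reproduces analytic Po within 2% relative
  sch <- trpv4_scheme(37)
  ev2 <- simulate_gating(sch, 400, seed = 77)
  expect_lt(abs(po_and_means(ev2)$po - equilibrium(sch)$po) /
              equilibrium(sch)$po, 0.02)
})
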