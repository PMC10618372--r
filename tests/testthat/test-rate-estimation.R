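test_that("interval likelihood matches the closed form for a two-state scheme", {
  sch <- two_state_scheme(2, 0.5)
  ev <- simulate_gating(sch, 5, seed = 3)
  cl <- ev$duration_ms[ev$class == "closed"]
  op <- ev$duration_ms[ev$class == "open"]
  # densities for all complete dwells, survival for the final one
  last <- ev[nrow(ev), ]
  rate_last <- if (last$class == "closed") 2 else 0.5
  ll_ref <- sum(dexp(cl, 2, log = TRUE)) + sum(dexp(op, 0.5, log = TRUE)) -
    dexp(last$duration_ms, rate_last, log = TRUE) +
    pexp(last$duration_ms, rate_last, lower.tail = FALSE, log.p = TRUE)
  expect_equal(interval_loglik(sch, ev, 0), ll_ref, tolerance = 1e-10)
})

test_that("likelihood peaks near the generating rates", {
  sch <- two_state_scheme(2, 0.5)
  ev <- simulate_gating(sch, 15, seed = 4)
  ll_true <- interval_loglik(sch, ev, 0)
  ll_pert <- interval_loglik(two_state_scheme(4, 1), ev, 0)
  expect_gt(ll_true, ll_pert)
})

test_that("log-likelihood is additive over concatenated records", {
  sch <- two_state_scheme(1, 0.8)
  a <- simulate_gating(sch, 8, seed = 5)
  b <- simulate_gating(sch, 8, seed = 6)
  lla <- interval_loglik(sch, a, 0)
  llb <- interval_loglik(sch, b, 0)
  ab <- event_table(c(a$class, b$class), c(a$duration_ms, b$duration_ms),
                    start_ms = NULL)
  # boundary terms: one survival term becomes a density and the classes may
  # clash at the join; tolerance covers those O(1) terms
  skip_if(a$class[nrow(a)] == b$class[1L])
  llab <- interval_loglik(sch, ab, 0)
  expect_lt(abs(llab - (lla + llb)) / abs(lla + llb), 0.005)
})

test_that("dead time zero reduces the corrected likelihood to the plain one", {
  sch <- two_state_scheme(1.5, 0.4)
  ev <- simulate_gating(sch, 5, seed = 7)
  expect_equal(interval_loglik(sch, ev, 0),
               interval_loglik(sch, ev, 1e-12), tolerance = 1e-6)
})

test_that("two-state MIL recovers rates within 5% from 1e4 dwells", {
  sch <- two_state_scheme(2, 0.5)
  ev <- simulate_gating(sch, 15, seed = 3)   # > 1e4 dwells
  expect_gt(nrow(ev), 1e4)
  fit <- fit_rates(ev, 1, 1, dead_time = 0, seed = 1)
  expect_lt(abs(fit$rates[["C1->O1"]] - 2) / 2, 0.05)
  expect_lt(abs(fit$rates[["O1->C1"]] - 0.5) / 0.5, 0.05)
  expect_equal(fit$convergence, 0L)
})

test_that("initialising at the truth leaves the optimum unchanged", {
  sch <- two_state_scheme(2, 0.5)
  ev <- simulate_gating(sch, 8, seed = 8)
  fit1 <- fit_rates(ev, 1, 1, dead_time = 0, init = sch)
  ll_truth_start <- fit1$loglik
  fit2 <- fit_rates(ev, 1, 1, dead_time = 0, seed = 2)
  expect_lt(abs(ll_truth_start - fit2$loglik), 1e-4)
})

test_that("estimator RMSE shrinks with the event count", {
  sch <- two_state_scheme(1, 1)
  errs <- vapply(c(2, 20), function(dur) {
    es <- vapply(1:3, function(s) {
      ev <- simulate_gating(sch, dur, seed = 100 + s)
      f <- fit_rates(ev, 1, 1, dead_time = 0, seed = s)
      mean((log(f$rates) - log(c(1, 1)))^2)
    }, numeric(1))
    sqrt(mean(es))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("missed-event correction removes the dead-time bias", {
  # 4 replicate records; bias measured as the mean log-rate error against
  # the SE of that mean. The first-order corrected operators are accurate
  # for dead times small against the mean dwell of the opposite class.
  sch <- two_state_scheme(2, 0.5)
  td <- 0.1
  n_rep <- 8L
  err_u <- err_c <- numeric(n_rep)
  for (s in seq_len(n_rep)) {
    ev <- apply_dead_time(simulate_gating(sch, 15, seed = 200 + s), td)
    fu <- fit_rates(ev, 1, 1, dead_time = 0, seed = s)
    fc <- suppressWarnings(fit_rates(ev, 1, 1, dead_time = td, seed = s))
    err_u[s] <- log(fu$rates[["C1->O1"]] / 2)
    err_c[s] <- log(fc$rates[["C1->O1"]] / 2)
  }
  se_u <- sd(err_u) / sqrt(n_rep)
  se_c <- sd(err_c) / sqrt(n_rep)
  # uncorrected: the apparent fast closed rate is biased low (tau high)
  expect_lt(mean(err_u), 0)
  expect_gt(abs(mean(err_u)) / se_u, 2)
  expect_lt(abs(mean(err_c)) / se_c, 2)
})

test_that("three-state-chain MIL recovers the closed time constants", {
  cl <- dwell_mixture("closed", c(0.8, 8), c(0.6, 0.4))
  op <- dwell_mixture("open", c(1.5, 6), c(0.5, 0.5))
  sch <- scheme_from_mixtures(cl, op)
  ev <- simulate_gating(sch, 60, seed = 9)
  fit <- suppressWarnings(fit_rates(ev, 2, 2, dead_time = 0, init = sch,
                                    seed = 1))
  got <- dwell_pdf(fit$scheme, "closed")
  expect_lt(max(abs(got$taus - cl$taus) / cl$taus), 0.15)
})
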