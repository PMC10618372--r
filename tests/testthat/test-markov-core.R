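test_that("dwell mixtures validate their invariants", {
  m <- dwell_mixture("closed", c(5.26, 0.58, 71.22), c(30, 58, 12), 22)
  expect_equal(m$taus, c(0.58, 5.26, 71.22))       # sorted ascending
  expect_equal(m$areas, c(0.58, 0.30, 0.12))       # percentages normalized
  expect_equal(sum(m$areas), 1)
  expect_error(dwell_mixture("closed", c(1, 1), c(0.5, 0.5)), "distinct")
  expect_error(dwell_mixture("closed", c(1, -2), c(0.5, 0.5)), "> 0")
  expect_error(dwell_mixture("closed", c(1, 2), c(0.5)), "same length")
})

test_that("kinetic schemes enforce structural invariants", {
  sch <- two_state_scheme(2, 0.5)
  expect_equal(rowSums(sch$Q), c(C1 = 0, O1 = 0), tolerance = 1e-12)
  expect_error(
    kinetic_scheme(c("a", "b"), c("closed", "closed"),
                   matrix(c(0, 1, 1, 0), 2, 2)),
    "open and .*closed")
  expect_error(
    kinetic_scheme(c("a", "b"), c("closed", "open"),
                   matrix(c(0, -1, 1, 0), 2, 2, byrow = TRUE)),
    ">= 0")
  # disconnected 4-state graph is rejected
  Q <- matrix(0, 4, 4)
  Q[1, 2] <- Q[2, 1] <- Q[3, 4] <- Q[4, 3] <- 1
  expect_error(
    kinetic_scheme(letters[1:4], c("closed", "open", "closed", "open"), Q),
    "irreducible")
})

test_that("Q10 scaling multiplies forward rates only and composes", {
  sch <- two_state_scheme(2, 0.5, reference_temperature = 37,
                          q10_forward = 15.6)
  same <- scale_rates_q10(sch, 37)
  expect_equal(same$Q, sch$Q)
  # 10 degrees of cooling divides the forward rate by Q10 exactly
  cooled <- scale_rates_q10(sch, 27)
  expect_equal(cooled$Q["C1", "O1"], 2 / 15.6)
  expect_equal(cooled$Q["O1", "C1"], 0.5)   # backward untouched
  sch2 <- two_state_scheme(2, 0.5, reference_temperature = 37, q10_forward = 2)
  expect_equal(scale_rates_q10(sch2, 27)$Q["C1", "O1"], 1)
  # composition: 37 -> 27 -> 22 equals 37 -> 22
  via <- scale_rates_q10(scale_rates_q10(sch, 27), 22)
  direct <- scale_rates_q10(sch, 22)
  expect_equal(via$Q, direct$Q, tolerance = 1e-12)
  expect_error(two_state_scheme(2, 0.5, q10_forward = -1), "positive")
})

test_that("equilibrium solves pi Q = 0 and yields Po and mean dwell times", {
  eq <- equilibrium(two_state_scheme(1, 1))
  expect_equal(eq$po, 0.5)
  eq2 <- equilibrium(two_state_scheme(3, 1))
  expect_equal(eq2$po, 0.75)
  expect_equal(eq2$mean_open, 1)     # 1 / closing rate
  expect_equal(eq2$mean_closed, 1 / 3)
  expect_equal(sum(eq2$occupancy), 1)
})

test_that("analytic Po matches a long stochastic simulation of the default scheme", {
  sch <- trpv4_scheme(37)
  ev <- simulate_gating(sch, 1000, seed = 42)
  po_mc <- sum(ev$duration_ms[ev$class == "open"]) / total_duration(ev)
  expect_gt(nrow(ev), 1e5 / 10)
  expect_lt(abs(po_mc - equilibrium(sch)$po), 0.01)
})

test_that("dwell_pdf recovers single-exponential and tabulated mixtures", {
  m <- dwell_pdf(two_state_scheme(2, 1), "open")
  expect_equal(m$taus, 1)
  expect_equal(m$areas, 1)
  # tabulated 22 C closed mixture is reproduced by the default scheme
  got <- dwell_pdf(trpv4_scheme(22), "closed")
  expect_equal(got$taus, c(0.58, 5.26, 71.22), tolerance = 1e-4)
  expect_equal(got$areas, c(0.58, 0.30, 0.12), tolerance = 1e-3)
})

test_that("analytic dwell distribution matches simulated dwells (KS)", {
  set.seed(5)
  sch <- trpv4_scheme(22)
  d <- sim_class_dwells(sch, "closed", 400, seed = 9)
  expect_gt(length(d), 1e4)
  ks <- suppressWarnings(stats::ks.test(d[seq(1, length(d), by = 3)],
                                        dwell_cdf_fun(sch, "closed")))
  expect_gt(ks$p.value, 0.01)
})

test_that("scheme_from_mixtures inverts mixtures on the chain topology", {
  # 1C/1O closed form: rates are reciprocal time constants
  sch <- scheme_from_mixtures(dwell_mixture("closed", 2, 1),
                              dwell_mixture("open", 5, 1))
  expect_equal(sch$Q["C1", "O1"], 0.5, tolerance = 1e-6)
  expect_equal(sch$Q["O1", "C1"], 0.2, tolerance = 1e-6)
  # tabulated 22 C closed + configured open round-trip
  cl <- trpv4_closed_mixtures()[["22"]]
  op <- trpv4_open_mixtures()[["22"]]
  sch22 <- scheme_from_mixtures(cl, op, temperature = 22)
  back_c <- dwell_pdf(sch22, "closed")
  back_o <- dwell_pdf(sch22, "open")
  expect_equal(back_c$taus, cl$taus, tolerance = 1e-4)
  expect_equal(back_c$areas, cl$areas, tolerance = 1e-3)
  expect_equal(back_o$taus, op$taus, tolerance = 1e-4)
  expect_equal(back_o$areas, op$areas, tolerance = 1e-3)
})

test_that("mixture round-trip holds for random chain-realizable mixtures", {
  set.seed(11)
  n_ok <- 0L
  for (i in 1:25) {
    # draw a random chain scheme, read off its mixtures, re-fit, compare
    nc <- sample(1:3, 1L)
    no <- sample(1:3, 1L)
    k <- nc + no
    Q <- matrix(0, k, k)
    for (j in seq_len(k - 1L)) {
      Q[j, j + 1L] <- exp(runif(1, log(0.02), log(2)))
      Q[j + 1L, j] <- exp(runif(1, log(0.02), log(2)))
    }
    states <- c(rev(paste0("C", seq_len(nc))), paste0("O", seq_len(no)))
    sch <- kinetic_scheme(states, c(rep("closed", nc), rep("open", no)), Q)
    mc <- dwell_pdf(sch, "closed")
    mo <- dwell_pdf(sch, "open")
    sch2 <- scheme_from_mixtures(mc, mo, seed = i)
    got_c <- dwell_pdf(sch2, "closed")
    got_o <- dwell_pdf(sch2, "open")
    expect_equal(got_c$taus, mc$taus, tolerance = 1e-4)
    expect_equal(got_o$taus, mo$taus, tolerance = 1e-4)
    expect_equal(got_c$areas, mc$areas, tolerance = 2e-3)
    expect_equal(got_o$areas, mo$areas, tolerance = 2e-3)
    n_ok <- n_ok + 1L
  }
  expect_equal(n_ok, 25L)
})

test_that("default scheme Po increases strictly with temperature", {
  po <- vapply(c(22, 32, 37), function(tt) equilibrium(trpv4_scheme(tt))$po,
               numeric(1))
  expect_true(all(diff(po) > 0))
  # interpolated scheme sits between its measured neighbours
  po27 <- equilibrium(trpv4_scheme(27))$po
  expect_gt(po27, po[1])
  expect_lt(po27, po[2])
  # per-transition Q10s are positive and finite
  q <- trpv4_q10()
  expect_true(all(is.finite(q) & q > 0))
})
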