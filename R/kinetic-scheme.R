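#' Continuous-time Markov kinetic scheme for a single channel
#'
#' Builds a validated kinetic scheme: a set of labelled states, each either
#' conducting (`"open"`) or non-conducting (`"closed"`), and a generator
#' (Q) matrix of transition rates in 1/ms. Off-diagonal entries are the
#' rates; the diagonal is recomputed as minus the row sum so that every row
#' sums to zero. The scheme carries unitary conductance (pS), reversal
#' potential (mV), a reference temperature (degrees C), the set of
#' "forward" transitions (those directed toward the open aggregate, which
#' carry the temperature dependence) and their Q10.
#'
#' @param states Character vector of state labels.
#' @param class_of_state Character vector, `"open"`/`"closed"` per state.
#' @param rates Square numeric matrix of transition rates (1/ms);
#'   off-diagonals must be >= 0; the diagonal is ignored and recomputed.
#' @param conductance Unitary conductance in pS.
#' @param vrev Reversal potential in mV.
#' @param reference_temperature Temperature (degrees C) at which the rates hold.
#' @param forward Two-column matrix (or data.frame) of state labels
#'   (`from`, `to`) designating forward transitions; default: none.
#' @param q10_forward Q10 applied to forward transitions by
#'   [scale_rates_q10()]. Either a single number or a named vector
#'   (`"from->to"`).
#' @return An object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(states, class_of_state, rates,
                           conductance = 59.7, vrev = -18.89,
                           reference_temperature = 22,
                           forward = NULL, q10_forward = 1) {
  states <- as.character(states)
  n <- length(states)
  if (n < 2L) stop("a scheme needs at least two states", call. = FALSE)
  if (anyDuplicated(states)) stop("state labels must be unique", call. = FALSE)
  class_of_state <- match.arg(class_of_state, c("open", "closed"),
                              several.ok = TRUE)
  if (length(class_of_state) != n) {
    stop("`class_of_state` must have one entry per state", call. = FALSE)
  }
  if (!any(class_of_state == "open") || !any(class_of_state == "closed")) {
    stop("scheme needs at least one open and one closed state", call. = FALSE)
  }
  rates <- as.matrix(rates)
  if (!all(dim(rates) == c(n, n))) {
    stop("`rates` must be a square matrix matching the number of states",
         call. = FALSE)
  }
  off <- rates
  diag(off) <- 0
  if (any(!is.finite(off)) || any(off < 0)) {
    stop("off-diagonal rates must be finite and >= 0", call. = FALSE)
  }
  Q <- off
  diag(Q) <- -rowSums(off)
  dimnames(Q) <- list(states, states)
  if (!is.null(forward)) {
    forward <- as.matrix(forward)
    if (ncol(forward) != 2L) stop("`forward` must have two columns", call. = FALSE)
    forward <- matrix(as.character(forward), ncol = 2L,
                      dimnames = list(NULL, c("from", "to")))
    bad <- !(forward[, 1L] %in% states) | !(forward[, 2L] %in% states)
    if (any(bad)) stop("unknown state label in `forward`", call. = FALSE)
    zero <- Q[cbind(forward[, 1L], forward[, 2L])] <= 0
    if (any(zero)) {
      stop("forward transitions must be a subset of the nonzero rates",
           call. = FALSE)
    }
  } else {
    forward <- matrix(character(0), ncol = 2L,
                      dimnames = list(NULL, c("from", "to")))
  }
  if (any(!is.finite(q10_forward)) || any(q10_forward <= 0)) {
    stop("`q10_forward` must be positive", call. = FALSE)
  }
  scheme <- structure(
    list(states = states, class_of_state = class_of_state, Q = Q,
         conductance = as.numeric(conductance), vrev = as.numeric(vrev),
         reference_temperature = as.numeric(reference_temperature),
         forward = forward, q10_forward = q10_forward),
    class = "kinetic_scheme"
  )
  if (!is_irreducible(scheme)) {
    stop("scheme error: connectivity graph is not irreducible", call. = FALSE)
  }
  scheme
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf(
    "<kinetic_scheme: %d states (%d open, %d closed), %g pS, Vrev %g mV, %g C>\n",
    length(x$states), sum(x$class_of_state == "open"),
    sum(x$class_of_state == "closed"), x$conductance, x$vrev,
    x$reference_temperature))
  print(round(x$Q, 5))
  invisible(x)
}

n_states <- function(scheme) length(scheme$states)

open_idx <- function(scheme) which(scheme$class_of_state == "open")
closed_idx <- function(scheme) which(scheme$class_of_state == "closed")
class_idx <- function(scheme, class) {
  if (class == "open") open_idx(scheme) else closed_idx(scheme)
}

#' @keywords internal
is_irreducible <- function(scheme) {
  A <- scheme$Q > 0
  diag(A) <- TRUE
  n <- nrow(A)
  # boolean transitive closure by repeated squaring
  R <- A
  for (i in seq_len(ceiling(log2(max(n, 2))))) {
    R <- (R %*% R) > 0
  }
  all(R)
}

#' Temperature-scale a kinetic scheme by Q10
#'
#' Multiplies every designated forward rate by
#' `q10 ^ ((target - reference) / 10)`, leaves the other rates unchanged,
#' recomputes the diagonal and updates the reference temperature. A Q10
#' above 1 therefore accelerates forward (open-ward) transitions on
#' warming.
#'
#' @param scheme A [kinetic_scheme()].
#' @param target_temperature Temperature in degrees C.
#' @return A new `kinetic_scheme` at the target temperature.
#' @export
scale_rates_q10 <- function(scheme, target_temperature) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (nrow(scheme$forward) == 0L) {
    warning("scheme has no designated forward transitions; rates unchanged")
  }
  q10 <- scheme$q10_forward
  if (any(!is.finite(q10)) || any(q10 <= 0)) {
    stop("parameter error: Q10 must be positive", call. = FALSE)
  }
  dT <- (target_temperature - scheme$reference_temperature) / 10
  Q <- scheme$Q
  for (r in seq_len(nrow(scheme$forward))) {
    from <- scheme$forward[r, 1L]
    to <- scheme$forward[r, 2L]
    key <- paste0(from, "->", to)
    q <- if (length(q10) > 1L) {
      if (!key %in% names(q10)) {
        stop("scheme error: no Q10 entry for forward transition ", key,
             call. = FALSE)
      }
      q10[[key]]
    } else {
      q10
    }
    Q[from, to] <- Q[from, to] * q^dT
  }
  diag(Q) <- 0
  kinetic_scheme(scheme$states, scheme$class_of_state, Q,
                 conductance = scheme$conductance, vrev = scheme$vrev,
                 reference_temperature = target_temperature,
                 forward = scheme$forward, q10_forward = scheme$q10_forward)
}

#' Equilibrium occupancy, open probability and mean class dwell times
#'
#' Solves the stationary distribution pi Q = 0 (sum pi = 1), and derives the
#' open probability Po (total stationary mass on open states) and the mean
#' open/closed dwell times as stationary class mass divided by the
#' equilibrium exit flux from the class.
#'
#' @param scheme A [kinetic_scheme()].
#' @return A list with `occupancy` (named), `po`, `mean_open` (ms),
#'   `mean_closed` (ms).
#' @export
equilibrium <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  Q <- scheme$Q
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(numeric(n), 1)
  pi <- as.numeric(qr.solve(A, b))
  pi[pi < 0 & pi > -1e-12] <- 0
  if (any(pi < 0)) stop("scheme error: negative stationary probability", call. = FALSE)
  pi <- pi / sum(pi)
  names(pi) <- scheme$states
  op <- open_idx(scheme)
  cl <- closed_idx(scheme)
  flux_oc <- sum(pi[op] * rowSums(Q[op, cl, drop = FALSE]))
  flux_co <- sum(pi[cl] * rowSums(Q[cl, op, drop = FALSE]))
  list(
    occupancy = pi,
    po = sum(pi[op]),
    mean_open = sum(pi[op]) / flux_oc,
    mean_closed = sum(pi[cl]) / flux_co
  )
}

# Entry probabilities into a class at stationarity: the distribution over
# class states at the moment the channel enters the class.
entry_probs <- function(scheme, class) {
  eq <- equilibrium(scheme)
  pi <- eq$occupancy
  into <- class_idx(scheme, class)
  from <- setdiff(seq_len(n_states(scheme)), into)
  w <- as.numeric(pi[from] %*% scheme$Q[from, into, drop = FALSE])
  w / sum(w)
}

#' Analytic dwell-time mixture of one conductance class
#'
#' The dwell-time density of an aggregated class is governed by the
#' within-class sub-generator: entering the class with the stationary entry
#' distribution phi, the dwell density is
#' `f(t) = phi exp(Qcc t) (-Qcc) 1`. Its spectral decomposition yields an
#' exponential mixture whose time constants are minus the reciprocal
#' eigenvalues of `Qcc` and whose areas come from the entry-weighted
#' eigenprojections.
#'
#' @param scheme A [kinetic_scheme()].
#' @param class `"open"` or `"closed"`.
#' @return A [dwell_mixture()].
#' @export
dwell_pdf <- function(scheme, class) {
  class <- match.arg(class, c("open", "closed"))
  sub <- class_idx(scheme, class)
  Qcc <- scheme$Q[sub, sub, drop = FALSE]
  phi <- entry_probs(scheme, class)
  dec <- mixture_of_subgenerator(Qcc, phi)
  if (dec$max_imag > 1e-8 * max(abs(dec$lambda_re)) + 1e-12) {
    stop("numerical error: within-class sub-generator has complex spectrum ",
         sprintf("(max imaginary part %.3g); no real exponential mixture",
                 dec$max_imag), call. = FALSE)
  }
  if (any(dec$areas < -1e-8)) {
    stop("numerical error: dwell decomposition yields negative area ",
         sprintf("(min %.3g); density is not a proper mixture", min(dec$areas)),
         call. = FALSE)
  }
  areas <- pmax(dec$areas, 0)
  dwell_mixture(class, dec$taus, areas / sum(areas),
                temperature = scheme$reference_temperature)
}

# Spectral decomposition of phi exp(Qcc t)(-Qcc)1 into sum c_k exp(lambda_k t).
# Returns taus (ascending), areas (= c_k * tau_k), and diagnostics.
mixture_of_subgenerator <- function(Qcc, phi) {
  ev <- eigen(Qcc)
  V <- ev$vectors
  lambda <- ev$values
  Vi <- solve(V)
  ones <- rep(1, nrow(Qcc))
  left <- as.vector(phi %*% V)
  right <- as.vector(Vi %*% (-Qcc %*% ones))
  ck <- left * right
  taus <- -1 / Re(lambda)
  areas <- Re(ck) * taus
  ord <- order(taus)
  list(taus = taus[ord], areas = areas[ord],
       lambda_re = Re(lambda), max_imag = max(abs(Im(ck)), abs(Im(lambda))))
}

#' Analytic dwell-time distribution function of one class
#'
#' Returns the exact survivor-based CDF `F(t) = 1 - phi exp(Qcc t) 1` as a
#' vectorized function, valid for any irreducible scheme (including ones
#' whose spectral decomposition is complex). Used as the reference
#' distribution when comparing analytic dwell theory against stochastic
#' simulation.
#'
#' @inheritParams dwell_pdf
#' @return A function of a numeric vector of dwell durations (ms).
#' @export
dwell_cdf_fun <- function(scheme, class) {
  class <- match.arg(class, c("open", "closed"))
  sub <- class_idx(scheme, class)
  Qcc <- scheme$Q[sub, sub, drop = FALSE]
  phi <- entry_probs(scheme, class)
  ev <- eigen(Qcc)
  Vi <- solve(ev$vectors)
  w <- as.vector(phi %*% ev$vectors) * as.vector(Vi %*% rep(1, nrow(Qcc)))
  lambda <- ev$values
  function(t) {
    surv <- Re(exp(outer(as.complex(t), lambda)) %*% w)
    pmin(pmax(1 - as.numeric(surv), 0), 1)
  }
}

#' Linear-chain gating scheme from closed and open dwell mixtures
#'
#' Constructs a kinetic scheme whose analytic dwell-time mixtures reproduce
#' the supplied closed and open mixtures, on a linear-chain topology
#' `Cn - ... - C1 - O1 - ... - Om` (the minimal uncoupled scheme able to
#' generate n closed and m open exponential components). Because the chain
#' has a single gateway transition, entry into either class always occurs
#' at the gateway state, and the two class sub-chains can be fitted
#' independently: each has `2k - 1` free rates against `2k - 1` mixture
#' constraints. Rates are found by penalized least squares in log-rate
#' space with deterministic multi-start; the result is verified to
#' round-trip the inputs (relative tau error <= 1e-4, area error <= 1e-3)
#' and an error is raised otherwise.
#'
#' @param closed,open [dwell_mixture()] objects with 1-3 components each.
#' @param topology Only `"linear"` is implemented.
#' @param conductance,vrev Channel conductance (pS) and reversal (mV).
#' @param temperature Reference temperature of the scheme; defaults to the
#'   closed mixture's temperature.
#' @param seed Seed for optimizer restarts (deterministic fit).
#' @return A `kinetic_scheme` with forward transitions designated along the
#'   closed-to-open direction of the chain.
#' @export
scheme_from_mixtures <- function(closed, open, topology = "linear",
                                 conductance = 59.7, vrev = -18.89,
                                 temperature = NULL, seed = 1L) {
  stopifnot(inherits(closed, "dwell_mixture"), inherits(open, "dwell_mixture"))
  if (closed$class != "closed" || open$class != "open") {
    stop("mixture classes must be 'closed' and 'open'", call. = FALSE)
  }
  topology <- match.arg(topology, "linear")
  nc <- length(closed$taus)
  no <- length(open$taus)
  if (nc > 3L || no > 3L) stop("1-3 components per class supported", call. = FALSE)
  if (is.null(temperature)) temperature <- closed$temperature

  fit_c <- fit_chain_class(closed, seed = seed)
  fit_o <- fit_chain_class(open, seed = seed + 1L)

  states <- c(rev(paste0("C", seq_len(nc))), paste0("O", seq_len(no)))
  cls <- c(rep("closed", nc), rep("open", no))
  n <- nc + no
  Q <- matrix(0, n, n, dimnames = list(states, states))
  # closed sub-chain occupies indices 1..nc with gateway C1 at index nc
  put_chain <- function(Q, idx, fit) {
    k <- length(idx)
    if (k > 1L) {
      for (j in seq_len(k - 1L)) {
        # idx ordered from gateway outward: rates$away[j], rates$back[j]
        Q[idx[j], idx[j + 1L]] <- fit$away[j]
        Q[idx[j + 1L], idx[j]] <- fit$back[j]
      }
    }
    Q
  }
  cl_order <- nc:1          # gateway first
  op_order <- (nc + 1L):n   # gateway first
  Q <- put_chain(Q, cl_order, fit_c)
  Q <- put_chain(Q, op_order, fit_o)
  Q[nc, nc + 1L] <- fit_c$exit   # C1 -> O1
  Q[nc + 1L, nc] <- fit_o$exit   # O1 -> C1
  forward <- cbind(states[seq_len(n - 1L)], states[2:n])
  scheme <- kinetic_scheme(states, cls, Q, conductance = conductance,
                           vrev = vrev, reference_temperature = temperature,
                           forward = forward)
  verify_roundtrip(scheme, closed, open)
  scheme
}

# Fit one class sub-chain (entered and exited at its gateway state) so its
# dwell mixture matches `mix`. Parameters (all 1/ms): exit rate from the
# gateway, plus away/back rates along the chain.
fit_chain_class <- function(mix, seed = 1L, n_restarts = 25L) {
  k <- length(mix$taus)
  if (k == 1L) {
    return(list(exit = 1 / mix$taus, away = numeric(0), back = numeric(0),
                residual = 0))
  }
  target_lt <- log(mix$taus)
  target_a <- mix$areas
  obj <- function(lp) {
    p <- exp(lp)
    dec <- chain_mixture(p, k)
    if (is.null(dec)) return(1e6)
    sum((log(pmax(dec$taus, 1e-12)) - target_lt)^2) +
      sum((dec$areas - target_a)^2)
  }
  init <- log(c(1 / mix$taus[1],
                rep(1 / mix$taus[-1], each = 2) *
                  rep(c(0.5, 1), times = k - 1L)))
  best <- NULL
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  for (r in seq_len(n_restarts)) {
    start <- if (r == 1L) init else init + stats::rnorm(length(init), 0, 0.8)
    fit <- try(stats::nlminb(start, obj, control = list(iter.max = 500)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    polish <- try(stats::optim(fit$par, obj, method = "BFGS",
                               control = list(maxit = 500, reltol = 1e-14)),
                  silent = TRUE)
    if (!inherits(polish, "try-error") && polish$value < fit$objective) {
      fit <- list(par = polish$par, objective = polish$value)
    }
    if (is.null(best) || fit$objective < best$objective) best <- fit
    if (best$objective < 1e-16) break
  }
  if (is.null(best)) stop("fit-failure: chain optimization did not run", call. = FALSE)
  p <- exp(best$par)
  dec <- chain_mixture(p, k)
  rel_tau <- max(abs(dec$taus - mix$taus) / mix$taus)
  abs_area <- max(abs(dec$areas - mix$areas))
  if (rel_tau > 1e-4 || abs_area > 1e-3) {
    stop(sprintf(
      "fit-failure: linear chain cannot realize the %s mixture (best residual: max tau rel err %.3g, max area err %.3g)",
      mix$class, rel_tau, abs_area), call. = FALSE)
  }
  list(exit = p[1], away = p[seq(2, 2 * k - 2, by = 2)],
       back = p[seq(3, 2 * k - 1, by = 2)], residual = best$objective)
}

# Dwell mixture of a k-state chain entered at state 1 (gateway), with exit
# rate p[1] from state 1 and away/back pairs p[2j], p[2j+1] along the chain.
chain_mixture <- function(p, k) {
  Qcc <- matrix(0, k, k)
  for (j in seq_len(k - 1L)) {
    Qcc[j, j + 1L] <- p[2L * j]
    Qcc[j + 1L, j] <- p[2L * j + 1L]
  }
  diag(Qcc) <- -(rowSums(Qcc) + c(p[1], numeric(k - 1L)))
  phi <- c(1, numeric(k - 1L))
  dec <- try(mixture_of_subgenerator(Qcc, phi), silent = TRUE)
  if (inherits(dec, "try-error") || any(!is.finite(dec$taus)) ||
      any(dec$taus <= 0)) {
    return(NULL)
  }
  dec
}

verify_roundtrip <- function(scheme, closed, open) {
  for (mix in list(closed, open)) {
    got <- dwell_pdf(scheme, mix$class)
    if (length(got$taus) != length(mix$taus) ||
        max(abs(got$taus - mix$taus) / mix$taus) > 1e-4 ||
        max(abs(got$areas - mix$areas)) > 1e-3) {
      stop("fit-failure: constructed scheme does not round-trip the ",
           mix$class, " mixture", call. = FALSE)
    }
  }
  invisible(TRUE)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (!is.null(state)) {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
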