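#' Interval likelihood of an idealized dwell sequence
#'
#' Log-likelihood of the alternating open/closed interval sequence under a
#' kinetic scheme, computed with matrix exponentials of the within-class
#' sub-generators. With a positive dead time the sub-generators are
#' replaced by first-order missed-event-corrected ones,
#' `eQ_AA = Q_AA + Q_AB (I - exp(Q_BB td)) (-Q_BB)^{-1} Q_BA`,
#' which accounts for sojourns in the opposite class shorter than the dead
#' time being absorbed into the observed dwell; each observed dwell of
#' duration t then contributes `exp(eQ_AA (t - td))` followed by the
#' corrected class-switch operator `Q_AB exp(Q_BB td)` (the entered class
#' must itself survive the dead time); the final dwell contributes its
#' survival only. At
#' `dead_time = 0` this reduces exactly to the uncorrected interval
#' likelihood.
#'
#' @param scheme A [kinetic_scheme()].
#' @param events An alternating [event_table()] with durations >=
#'   `dead_time`.
#' @param dead_time Dead time in ms (0 disables the missed-event
#'   correction).
#' @return The log-likelihood (a scalar).
#' @export
interval_loglik <- function(scheme, events, dead_time = 0) {
  stopifnot(inherits(scheme, "kinetic_scheme"), inherits(events, "event_table"))
  if (nrow(events) == 0L) stop("empty event table", call. = FALSE)
  if (any(events$duration_ms < dead_time - 1e-9)) {
    stop("input error: dwells shorter than the dead time", call. = FALSE)
  }
  parts <- mil_parts(scheme, dead_time)
  if (is.null(parts)) return(-Inf)
  cls <- as.integer(events$class == "open")
  v0 <- mil_entry(scheme, events$class[1L])
  .mil_propagate(events$duration_ms, cls, dead_time, v0,
                 parts$closed$V, parts$closed$lam, parts$closed$M2,
                 parts$open$V, parts$open$lam, parts$open$M2,
                 parts$closed$Vi, parts$open$Vi)
}

# entry distribution over the states of the first dwell's class
mil_entry <- function(scheme, first_class) {
  entry_probs(scheme, first_class)
}

# Spectral pieces of the (dead-time-corrected) class sub-generators.
# Returns NULL when a spectrum is not real (the optimizer treats that as
# an invalid point).
mil_parts <- function(scheme, dead_time) {
  cl <- closed_idx(scheme)
  op <- open_idx(scheme)
  Q <- scheme$Q
  part <- function(a, b) {
    Qaa <- Q[a, a, drop = FALSE]
    Qab <- Q[a, b, drop = FALSE]
    if (dead_time > 0) {
      Qbb <- Q[b, b, drop = FALSE]
      Qba <- Q[b, a, drop = FALSE]
      E <- expm_small(Qbb * dead_time)
      eQ <- Qaa + Qab %*% (diag(nrow(Qbb)) - E) %*% solve(-Qbb) %*% Qba
      Qab <- Qab %*% E  # switch operator: excursion must survive the dead time
    } else {
      eQ <- Qaa
    }
    ev <- eigen(eQ)
    if (max(abs(Im(ev$values))) > 1e-9 * max(abs(Re(ev$values)), 1)) {
      return(NULL)
    }
    V <- Re(ev$vectors)
    Vi <- try(solve(V), silent = TRUE)
    if (inherits(Vi, "try-error")) return(NULL)
    list(V = V, Vi = Vi, lam = Re(ev$values), M2 = Vi %*% Qab)
  }
  pc <- part(cl, op)
  po <- part(op, cl)
  if (is.null(pc) || is.null(po)) return(NULL)
  list(closed = pc, open = po)
}

# matrix exponential of a small matrix via its eigendecomposition, with a
# scaled Taylor fallback for (near-)defective cases
expm_small <- function(M) {
  ev <- try(eigen(M), silent = TRUE)
  if (!inherits(ev, "try-error")) {
    Vi <- try(solve(ev$vectors), silent = TRUE)
    if (!inherits(Vi, "try-error") &&
        kappa(ev$vectors) < 1e10) {
      return(Re(ev$vectors %*% diag(exp(ev$values), nrow(M)) %*% Vi))
    }
  }
  # scaling and squaring with a Taylor core
  s <- max(0L, ceiling(log2(max(norm(M, "O"), 1e-16))) + 2L)
  A <- M / 2^s
  E <- diag(nrow(M))
  term <- E
  for (k in 1:12) {
    term <- term %*% A / k
    E <- E + term
  }
  for (k in seq_len(s)) E <- E %*% E
  E
}

#' Maximum-interval-likelihood estimation of kinetic rates
#'
#' Fits the transition rates of a linear-chain scheme (Cn-...-C1-O1-...-Om)
#' to an idealized dwell sequence by maximising the missed-event-corrected
#' interval likelihood ([interval_loglik()]) over log-rates, quasi-Newton
#' with deterministic restarts. Standard errors of the log-rates come from
#' the observed information (numerical Hessian at the optimum).
#'
#' @param events An alternating [event_table()].
#' @param n_closed,n_open Number of closed and open states of the chain.
#' @param dead_time Dead time in ms (0: no missed-event correction).
#' @param init Optional initial `kinetic_scheme` (e.g. the truth in
#'   simulation studies, or a scheme built from dwell-mixture fits).
#'   Default: built by [scheme_from_mixtures()] from likelihood-selected
#'   mixture fits of the two dwell distributions.
#' @param seed Seed controlling restarts.
#' @param conductance,vrev Carried into the returned scheme.
#' @return A list: `scheme` (fitted), `loglik`, `rates` (named vector,
#'   1/ms), `se_log_rate` (named; NA where the observed information is
#'   singular), `convergence` (0 = converged), `n_dwells`.
#' @export
fit_rates <- function(events, n_closed = 1L, n_open = 1L, dead_time = 0,
                      init = NULL, seed = 1L, conductance = 59.7,
                      vrev = -18.89) {
  stopifnot(inherits(events, "event_table"))
  n_free <- 2L * (n_closed - 1L) + 2L * (n_open - 1L) + 2L
  if (nrow(events) < 10L * n_free) {
    stop("too few events for the number of free rates", call. = FALSE)
  }
  chain <- chain_layout(n_closed, n_open)
  if (is.null(init)) {
    init <- init_from_mixtures(events, n_closed, n_open, dead_time,
                               conductance, vrev, seed)
  }
  p0 <- log(pmin(pmax(init$Q[chain$pairs], 1e-6), 1e3))
  nll <- function(lp) {
    Q <- matrix(0, chain$n, chain$n, dimnames = list(chain$states, chain$states))
    Q[chain$pairs] <- exp(lp)
    diag(Q) <- -rowSums(Q)
    sch <- structure(list(states = chain$states,
                          class_of_state = chain$cls, Q = Q),
                     class = "kinetic_scheme")
    ll <- tryCatch(interval_loglik(sch, events, dead_time),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  fit <- stats::nlminb(p0, nll, lower = log(1e-6), upper = log(1e3),
                       control = list(iter.max = 1000, eval.max = 3000))
  H <- try(stats::optimHess(fit$par, nll), silent = TRUE)
  se <- rep(NA_real_, n_free)
  if (!inherits(H, "try-error")) {
    cov <- try(solve(H), silent = TRUE)
    if (!inherits(cov, "try-error")) {
      d <- diag(cov)
      se[d > 0] <- sqrt(d[d > 0])
      flat <- !is.finite(se) | se > 5
      if (any(flat)) {
        warning("flat likelihood directions detected for: ",
                paste(chain$labels[flat], collapse = ", "),
                "; rates in these directions are poorly identified")
      }
    }
  }
  Q <- matrix(0, chain$n, chain$n, dimnames = list(chain$states, chain$states))
  Q[chain$pairs] <- exp(fit$par)
  scheme <- kinetic_scheme(chain$states, chain$cls, Q,
                           conductance = conductance, vrev = vrev,
                           reference_temperature = NA_real_,
                           forward = chain$forward)
  rates <- exp(fit$par)
  names(rates) <- names(se) <- chain$labels
  list(scheme = scheme, loglik = -fit$objective, rates = rates,
       se_log_rate = se, convergence = fit$convergence,
       n_dwells = nrow(events))
}

chain_layout <- function(n_closed, n_open) {
  states <- c(rev(paste0("C", seq_len(n_closed))), paste0("O", seq_len(n_open)))
  cls <- c(rep("closed", n_closed), rep("open", n_open))
  n <- n_closed + n_open
  pairs <- rbind(cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L),
                 cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L)))
  labels <- paste0(states[pairs[, 1L]], "->", states[pairs[, 2L]])
  forward <- cbind(states[seq_len(n - 1L)], states[2:n])
  list(states = states, cls = cls, n = n, pairs = pairs, labels = labels,
       forward = forward)
}

init_from_mixtures <- function(events, n_closed, n_open, dead_time,
                               conductance, vrev, seed) {
  cl <- dwells_of_class(events, "closed")
  op <- dwells_of_class(events, "open")
  fc <- fit_mixture(cl, n_closed, dead_time, "closed", seed = seed)
  fo <- fit_mixture(op, n_open, dead_time, "open", seed = seed)
  sch <- try(scheme_from_mixtures(fc$mixture, fo$mixture,
                                  conductance = conductance,
                                  vrev = vrev, seed = seed),
             silent = TRUE)
  if (!inherits(sch, "try-error")) return(sch)
  # heuristic fallback when the fitted mixtures are not chain-realizable
  chain <- chain_layout(n_closed, n_open)
  Q <- matrix(0, chain$n, chain$n, dimnames = list(chain$states, chain$states))
  tc <- rep_len(fc$mixture$taus, n_closed)
  to <- rep_len(fo$mixture$taus, n_open)
  rates_c <- 1 / tc
  rates_o <- 1 / to
  Q[chain$pairs] <- 0.5
  Q[n_closed, n_closed + 1L] <- rates_c[1L]
  Q[n_closed + 1L, n_closed] <- rates_o[1L]
  if (n_closed > 1L) {
    for (j in 2:n_closed) {
      Q[n_closed - j + 1L, n_closed - j + 2L] <- rates_c[j]
      Q[n_closed - j + 2L, n_closed - j + 1L] <- rates_c[j] / 2
    }
  }
  if (n_open > 1L) {
    for (j in 2:n_open) {
      Q[n_closed + j, n_closed + j - 1L] <- rates_o[j] / 2
      Q[n_closed + j - 1L, n_closed + j] <- rates_o[j]
    }
  }
  kinetic_scheme(chain$states, chain$cls, Q, conductance = conductance,
                 vrev = vrev, forward = chain$forward)
}
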