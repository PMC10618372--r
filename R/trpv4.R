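#' Default Trpv4-like gating scheme at a given temperature
#'
#' Builds the package's default 3-closed/3-open linear-chain scheme for the
#' PVN Trpv4-like channel. At the three measured temperatures (22, 32,
#' 37 degrees C) the scheme is constructed by [scheme_from_mixtures()] from
#' the tabulated closed mixture ([trpv4_closed_mixtures()]) and the
#' configured open mixture ([trpv4_open_mixtures()]). At any other
#' temperature each transition rate is obtained from a log-linear
#' regression of its fitted values on temperature across the three measured
#' schemes — i.e. an effective per-transition Q10 — which honours both the
#' measured endpoints and the Q10 mechanism of temperature dependence.
#'
#' @param temperature Temperature in degrees C.
#' @return A `kinetic_scheme` (conductance 59.7 pS, reversal -18.89 mV).
#' @examples
#' sch <- trpv4_scheme(37)
#' equilibrium(sch)$po
#' @export
trpv4_scheme <- function(temperature = 22) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature))
  fitted <- trpv4_fitted_schemes()
  key <- as.character(temperature)
  if (key %in% names(fitted)) return(fitted[[key]])
  reg <- trpv4_rate_regression()
  template <- fitted[["22"]]
  Q <- template$Q * 0
  for (i in seq_len(nrow(reg$pairs))) {
    from <- reg$pairs[i, 1L]
    to <- reg$pairs[i, 2L]
    Q[from, to] <- exp(reg$intercept[i] + reg$slope[i] * temperature)
  }
  kinetic_scheme(template$states, template$class_of_state, Q,
                 conductance = template$conductance, vrev = template$vrev,
                 reference_temperature = temperature,
                 forward = template$forward)
}

trpv4_fitted_schemes <- function() {
  cache_get_or("trpv4_fitted_schemes", function() {
    cl <- trpv4_closed_mixtures()
    op <- trpv4_open_mixtures()
    out <- lapply(names(cl), function(tt) {
      scheme_from_mixtures(cl[[tt]], op[[tt]], temperature = as.numeric(tt))
    })
    names(out) <- names(cl)
    out
  })
}

# log-linear regression of each transition rate on temperature across the
# three fitted schemes
trpv4_rate_regression <- function() {
  cache_get_or("trpv4_rate_regression", function() {
    fitted <- trpv4_fitted_schemes()
    temps <- as.numeric(names(fitted))
    template <- fitted[[1L]]
    nz <- which(template$Q > 0, arr.ind = TRUE)
    pairs <- cbind(template$states[nz[, 1L]], template$states[nz[, 2L]])
    slope <- intercept <- numeric(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      lk <- vapply(fitted, function(s) log(s$Q[pairs[i, 1L], pairs[i, 2L]]),
                   numeric(1))
      co <- stats::coef(stats::lm(lk ~ temps))
      intercept[i] <- co[[1L]]
      slope[i] <- co[[2L]]
    }
    list(pairs = pairs, intercept = intercept, slope = slope)
  })
}

#' Effective per-transition Q10 of the default Trpv4-like scheme
#'
#' The Q10 of each transition implied by the log-linear regression of the
#' fitted per-temperature rates on temperature (`Q10 = exp(10 * slope)`).
#'
#' @return Named numeric vector (`"from->to"`).
#' @export
trpv4_q10 <- function() {
  reg <- trpv4_rate_regression()
  q <- exp(10 * reg$slope)
  names(q) <- paste0(reg$pairs[, 1L], "->", reg$pairs[, 2L])
  q
}
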