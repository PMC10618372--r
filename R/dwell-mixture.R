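#' Exponential dwell-time mixture
#'
#' A mixture of exponential components describing the dwell-time
#' distribution of one conductance class (open or closed) of a single
#' channel. This is the object maximum-likelihood dwell fits return and the
#' object from which kinetic schemes can be constructed.
#'
#' @param class `"open"` or `"closed"`.
#' @param taus Time constants in ms, strictly positive. Stored sorted
#'   ascending (areas are permuted along).
#' @param areas Fractional areas, summing to 1. Values given as percentages
#'   (summing to ~100) are accepted and renormalized.
#' @param temperature Recording temperature in degrees C (optional metadata).
#' @return An object of class `dwell_mixture`: a list with elements
#'   `class`, `taus`, `areas`, `temperature`.
#' @examples
#' dwell_mixture("closed", taus = c(0.58, 5.26, 71.22), areas = c(58, 30, 12))
#' @export
dwell_mixture <- function(class, taus, areas, temperature = NA_real_) {
  class <- match.arg(class, c("open", "closed"))
  taus <- as.numeric(taus)
  areas <- as.numeric(areas)
  if (length(taus) != length(areas)) {
    stop("`taus` and `areas` must have the same length", call. = FALSE)
  }
  if (length(taus) < 1L) stop("mixture needs at least one component", call. = FALSE)
  if (any(!is.finite(taus)) || any(taus <= 0)) {
    stop("all time constants must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(areas)) || any(areas < 0)) {
    stop("all areas must be finite and >= 0", call. = FALSE)
  }
  s <- sum(areas)
  if (s <= 0) stop("areas sum to zero", call. = FALSE)
  # accept percentage input (Table-style rows often sum to 99 or 100)
  areas <- areas / s
  ord <- order(taus)
  taus <- taus[ord]
  areas <- areas[ord]
  if (any(diff(taus) <= 0)) {
    stop("time constants must be distinct", call. = FALSE)
  }
  structure(
    list(class = class, taus = taus, areas = areas,
         temperature = as.numeric(temperature)),
    class = "dwell_mixture"
  )
}

#' @export
print.dwell_mixture <- function(x, ...) {
  cat(sprintf("<dwell_mixture: %s, %d component(s)%s>\n", x$class,
              length(x$taus),
              if (is.finite(x$temperature)) sprintf(", %g C", x$temperature) else ""))
  print(data.frame(tau_ms = x$taus, area_pct = 100 * x$areas))
  invisible(x)
}

#' Mixture density, distribution and moments
#'
#' `dmixexp` and `pmixexp` evaluate the density and CDF of an exponential
#' mixture; `rmixexp` draws from it; `mean_dwell` returns its mean.
#'
#' @param x,q,n Evaluation points / sample size.
#' @param mixture A [dwell_mixture()].
#' @return Numeric vector.
#' @keywords internal
#' @export
dmixexp <- function(x, mixture) {
  f <- numeric(length(x))
  for (k in seq_along(mixture$taus)) {
    f <- f + mixture$areas[k] / mixture$taus[k] * exp(-x / mixture$taus[k])
  }
  f[x < 0] <- 0
  f
}

#' @rdname dmixexp
#' @export
pmixexp <- function(q, mixture) {
  p <- numeric(length(q))
  for (k in seq_along(mixture$taus)) {
    p <- p + mixture$areas[k] * (1 - exp(-pmax(q, 0) / mixture$taus[k]))
  }
  p
}

#' @rdname dmixexp
#' @export
rmixexp <- function(n, mixture) {
  k <- sample.int(length(mixture$taus), n, replace = TRUE, prob = mixture$areas)
  stats::rexp(n, rate = 1) * mixture$taus[k]
}

#' @rdname dmixexp
#' @export
mean_dwell <- function(mixture) {
  sum(mixture$areas * mixture$taus)
}

#' Printed closed-dwell mixtures of the PVN Trpv4-like channel
#'
#' Closed-class dwell-time mixtures of the Trpv4-like channel at 22, 32 and
#' 37 degrees C (time constants in ms, areas as percentages renormalized to
#' fractions), as obtained by maximum-likelihood fitting of single-channel
#' records.
#'
#' @return A named list of three `dwell_mixture` objects (`"22"`, `"32"`,
#'   `"37"`).
#' @export
trpv4_closed_mixtures <- function() {
  list(
    "22" = dwell_mixture("closed", c(0.58, 5.26, 71.22), c(58, 30, 12), 22),
    "32" = dwell_mixture("closed", c(0.75, 5.87, 49.96), c(65, 27, 7), 32),
    "37" = dwell_mixture("closed", c(1.24, 7.28, 82.19), c(69, 24, 7), 37)
  )
}

#' Default open-dwell mixtures of the PVN Trpv4-like channel
#'
#' Open-class mixtures are not tabulated for this channel; these defaults
#' are package configuration constants chosen so that (i) the fast open
#' component is temperature-insensitive while the two slower components
#' shorten on cooling, and (ii) analytic open probability falls markedly on
#' cooling, driven by shorter mean open times. They are not measured values
#' and are documented as free configuration in the methods vignette.
#'
#' @return A named list of three `dwell_mixture` objects (`"22"`, `"32"`,
#'   `"37"`).
#' @export
trpv4_open_mixtures <- function() {
  list(
    "22" = dwell_mixture("open", c(1.5, 4, 10), c(0.50, 0.30, 0.20), 22),
    "32" = dwell_mixture("open", c(1.5, 8, 25), c(0.30, 0.40, 0.30), 32),
    "37" = dwell_mixture("open", c(1.5, 12, 60), c(0.15, 0.35, 0.50), 37)
  )
}
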