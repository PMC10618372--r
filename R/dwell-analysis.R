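#' Log-binned dwell-time histogram (Sigworth-Sine display)
#'
#' Bins dwell durations into logarithmically spaced bins for display with a
#' square-root ordinate, in which each exponential component of the
#' dwell-time distribution appears as a peak located at its time constant.
#' Binning is for display only; fitting works on the unbinned dwells.
#'
#' @param dwells Dwell durations, ms (non-empty, positive).
#' @param bins_per_decade Number of bins per decade of time.
#' @return A list of class `log_binned_histogram` with `edges` (ms),
#'   `counts`, `mids` (geometric bin centres), `ordinate = "sqrt"`.
#' @export
log_bin <- function(dwells, bins_per_decade = 10) {
  dwells <- as.numeric(dwells)
  if (length(dwells) == 0L) stop("no dwells to bin", call. = FALSE)
  if (any(dwells <= 0)) stop("dwells must be positive", call. = FALSE)
  lo <- floor(log10(min(dwells)) * bins_per_decade) / bins_per_decade
  hi <- ceiling(log10(max(dwells)) * bins_per_decade) / bins_per_decade
  if (hi <= lo) hi <- lo + 1 / bins_per_decade
  edges <- 10^seq(lo, hi, by = 1 / bins_per_decade)
  counts <- graphics::hist(dwells, breaks = edges, plot = FALSE,
                           right = FALSE, include.lowest = TRUE)$counts
  # hist() drops points equal to the right edge under right = FALSE
  counts[length(counts)] <- counts[length(counts)] + sum(dwells == edges[length(edges)])
  structure(list(edges = edges, counts = counts,
                 mids = sqrt(edges[-1L] * edges[-length(edges)]),
                 bins_per_decade = bins_per_decade, ordinate = "sqrt",
                 n = length(dwells)),
            class = "log_binned_histogram")
}

#' @export
print.log_binned_histogram <- function(x, ...) {
  cat(sprintf("<log_binned_histogram: %d dwells, %d bins (%g/decade), sqrt ordinate>\n",
              x$n, length(x$counts), x$bins_per_decade))
  invisible(x)
}

#' @export
plot.log_binned_histogram <- function(x, ...) {
  graphics::plot(x$mids, sqrt(x$counts), log = "x", type = "s",
                 xlab = "dwell time (ms)", ylab = expression(sqrt(count)), ...)
  invisible(x)
}

#' Maximum-likelihood exponential-mixture fit of dwell times
#'
#' Fits a mixture of 1-3 exponentials to unbinned dwell durations by
#' maximum likelihood, with left truncation at the dead time: the model is
#' the underlying mixture conditioned on the dwell exceeding `dead_time`,
#' so the reported time constants and areas refer to the full
#' (untruncated) distribution. A truncated exponential mixture is, after
#' shifting by the dead time, again an exponential mixture with reweighted
#' areas, so fitting uses EM on the shifted dwells with deterministic
#' multi-start and the original areas are recovered as
#' `a_k proportional to w_k exp(dead_time / tau_k)`.
#'
#' @param dwells Dwell durations in ms, all >= `dead_time`.
#' @param n_components 1, 2 or 3.
#' @param dead_time Dead time (ms) the dwells were resolved at.
#' @param class Conductance class label carried into the result.
#' @param seed Seed for the restarts (deterministic fit).
#' @param n_restarts Number of EM starts.
#' @return A list of class `mixture_fit`: `mixture` (a [dwell_mixture()]),
#'   `loglik`, `n`, `n_components`, `dead_time`, `converged`.
#' @export
fit_mixture <- function(dwells, n_components, dead_time = 0,
                        class = "closed", seed = 1L, n_restarts = 10L) {
  dwells <- as.numeric(dwells)
  n <- length(dwells)
  if (n == 0L) stop("no dwells to fit", call. = FALSE)
  if (!n_components %in% 1:3) stop("n_components must be 1, 2 or 3", call. = FALSE)
  if (any(dwells < dead_time - 1e-9)) {
    stop("all dwells must be >= dead_time", call. = FALSE)
  }
  s <- pmax(dwells - dead_time, 0)
  if (n_components == 1L) {
    tau <- mean(s)
    ll <- sum(stats::dexp(s, rate = 1 / tau, log = TRUE))
    fit <- list(taus = tau, w = 1, loglik = ll, converged = TRUE)
  } else {
    fit <- with_seed(seed, em_expmix_multistart(s, n_components, n_restarts))
  }
  areas <- fit$w * exp(dead_time / fit$taus)
  areas <- areas / sum(areas)
  # collapse components the data cannot distinguish
  taus <- fit$taus
  mix <- try(dwell_mixture(class, taus, areas), silent = TRUE)
  if (inherits(mix, "try-error")) {
    keep <- !duplicated(signif(taus, 8))
    agg <- tapply(areas, signif(taus, 8), sum)
    mix <- dwell_mixture(class, as.numeric(names(agg)), as.numeric(agg))
    warning("components collapsed during fitting; fewer than requested are distinguishable")
    fit$converged <- FALSE
  }
  structure(list(mixture = mix, loglik = fit$loglik, n = n,
                 n_components = length(mix$taus), dead_time = dead_time,
                 converged = fit$converged),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit: %d %s dwells, %d component(s), logLik %.2f, dead time %g ms>\n",
              x$n, x$mixture$class, x$n_components, x$loglik, x$dead_time))
  print(data.frame(tau_ms = x$mixture$taus, area_pct = 100 * x$mixture$areas))
  invisible(x)
}

em_expmix_multistart <- function(s, k, n_restarts) {
  n <- length(s)
  qs <- stats::quantile(s[s > 0], probs = seq(0.15, 0.9, length.out = k))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    taus <- if (r == 1L) as.numeric(qs) else as.numeric(qs) * exp(stats::rnorm(k, 0, 0.7))
    taus <- pmax(taus, 1e-4)
    w <- rep(1 / k, k)
    fit <- em_expmix(s, taus, w)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best
}

em_expmix <- function(s, taus, w, max_iter = 500L, tol = 1e-8) {
  n <- length(s)
  k <- length(taus)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ld <- vapply(seq_len(k),
                 function(j) log(w[j]) - log(taus[j]) - s / taus[j],
                 numeric(n))
    m <- do.call(pmax, as.data.frame(ld))
    lse <- m + log(rowSums(exp(ld - m)))
    ll <- sum(lse)
    resp <- exp(ld - lse)
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-12)
    taus <- pmax(colSums(resp * s) / nk, 1e-6)
    w <- nk / n
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  ord <- order(taus)
  list(taus = taus[ord], w = w[ord], loglik = ll, converged = converged)
}

#' Likelihood-ratio selection of the number of exponential components
#'
#' Fits mixtures with increasing numbers of components and keeps adding a
#' component while twice the log-likelihood gain exceeds the chi-squared
#' critical value with 2 degrees of freedom per added component (one time
#' constant plus one area), at the given confidence level.
#'
#' @inheritParams fit_mixture
#' @param max_n Largest number of components considered.
#' @param conf Confidence level of the test (0.95 as standard).
#' @return The selected `mixture_fit`, with the fits of every candidate
#'   size in `$candidates` and the test trace in `$llr`.
#' @export
select_components <- function(dwells, max_n = 3, conf = 0.95, dead_time = 0,
                              class = "closed", seed = 1L) {
  fits <- vector("list", max_n)
  llr <- numeric(0)
  crit <- stats::qchisq(conf, df = 2)
  fits[[1L]] <- fit_mixture(dwells, 1L, dead_time, class, seed = seed)
  chosen <- 1L
  for (k in seq_len(max_n - 1L) + 1L) {
    fits[[k]] <- fit_mixture(dwells, k, dead_time, class, seed = seed)
    stat <- 2 * (fits[[k]]$loglik - fits[[chosen]]$loglik)
    llr <- c(llr, stat)
    if (is.finite(stat) && stat > crit && fits[[k]]$n_components == k) {
      chosen <- k
    } else {
      break
    }
  }
  out <- fits[[chosen]]
  out$candidates <- fits[!vapply(fits, is.null, logical(1))]
  out$llr <- llr
  out
}

#' Open probability and mean dwell times from an idealized record
#'
#' `po` is the fraction of the total record spent open (all dwells); the
#' mean open/closed durations exclude the first and last dwell of the
#' record, whose durations are censored.
#'
#' @param events An [event_table()].
#' @return A list with `po`, `mean_open`, `mean_closed`, `n_open`,
#'   `n_closed`, `total_ms`.
#' @export
po_and_means <- function(events) {
  if (nrow(events) == 0L) stop("empty event table", call. = FALSE)
  tot <- total_duration(events)
  open_t <- sum(events$duration_ms[events$class == "open"])
  op <- dwells_of_class(events, "open")
  cl <- dwells_of_class(events, "closed")
  list(po = open_t / tot,
       mean_open = if (length(op)) mean(op) else NA_real_,
       mean_closed = if (length(cl)) mean(cl) else NA_real_,
       n_open = length(op), n_closed = length(cl), total_ms = tot)
}
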