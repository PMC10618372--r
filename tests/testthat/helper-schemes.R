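# shared fixtures: small schemes and random-scheme generators, built in code

two_state_scheme <- function(k_open = 1, k_close = 1, ...) {
  kinetic_scheme(c("C1", "O1"), c("closed", "open"),
                 matrix(c(0, k_open, k_close, 0), 2, 2, byrow = TRUE),
                 forward = cbind("C1", "O1"), ...)
}

# random reversible scheme: random stationary distribution + symmetric
# edge weights on a random connected graph (spanning tree plus extras),
# so all within-class spectra are real
random_reversible_scheme <- function(n_states = NULL) {
  n <- if (is.null(n_states)) sample(2:6, 1L) else n_states
  repeat {
    cls <- sample(c("open", "closed"), n, replace = TRUE)
    if (any(cls == "open") && any(cls == "closed")) break
  }
  pi <- rgamma(n, 2, 1)
  pi <- pi / sum(pi)
  W <- matrix(0, n, n)
  perm <- sample.int(n)
  for (i in seq_len(n - 1L)) {          # spanning tree
    a <- perm[i]; b <- perm[i + 1L]
    W[a, b] <- W[b, a] <- rgamma(1, 2, 1)
  }
  extra <- which(upper.tri(W) & W == 0)
  if (length(extra)) {
    add <- extra[runif(length(extra)) < 0.3]
    W[add] <- rgamma(length(add), 2, 1)
    W[lower.tri(W)] <- t(W)[lower.tri(W)]
  }
  Q <- W / pi                            # pi_i q_ij = w_ij: reversible
  Q <- Q * (0.5 / mean(Q[Q > 0]))        # rates around 0.5 / ms
  kinetic_scheme(paste0("S", seq_len(n)), cls, Q)
}

# dwell durations of one class straight from a simulated event table
sim_class_dwells <- function(scheme, class, duration_s, seed) {
  ev <- simulate_gating(scheme, duration_s, seed = seed)
  dwells_of_class(ev, class)
}
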