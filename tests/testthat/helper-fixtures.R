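# Shared fixtures: small count tables and an independent compound sampler
# used as an oracle for the beta-binomial construction.

make_counts <- function(u, v, pairs = NULL) {
  paired_counts(matrix(u, nrow = 1), matrix(v, nrow = 1), pairs = pairs)
}

# Independent compound draw: M ~ Beta(alpha, beta) on the proportion scale,
# then u ~ Binomial(N, p(M)) with the scaling map applied to each draw.
# Deliberately built from base R primitives, not the package pmf.
rbb_compound <- function(n, N, Pi, phi, L = 1, L_prime = 1) {
  if (phi == 0) {
    p <- Pi * L / (Pi * L + (1 - Pi) * L_prime)
    return(rbinom(n, N, p))
  }
  a <- Pi * (1 - phi) / phi
  b <- (1 - Pi) * (1 - phi) / phi
  M <- rbeta(n, a, b)
  p <- M * L / (M * L + (1 - M) * L_prime)
  rbinom(n, N, p)
}

# Exhaustive grid maximiser of the one-tuple likelihood under a single
# replicate group with unit scaling, used as the optimizer oracle. Written
# directly from the log-gamma form of the pmf, independent of the package
# likelihood code, and vectorised over the proportion grid.
grid_fit <- function(u, v, n_pi = 200, n_phi = 200, phi_max = 0.995) {
  pis <- seq(0.0005, 0.9995, length.out = n_pi)
  phis <- seq(0, phi_max, length.out = n_phi)
  const <- sum(lchoose(u + v, u))
  best <- c(ll = -Inf, Pi = NA, phi = NA)
  for (phi in phis) {
    if (phi == 0) {
      ll <- colSums(outer(u, log(pis)) + outer(v, log(1 - pis)))
    } else {
      a <- pis * (1 - phi) / phi
      b <- (1 - pis) * (1 - phi) / phi
      lb0 <- lgamma(a) + lgamma(b) - lgamma(a + b)
      ll <- numeric(n_pi)
      for (i in seq_along(u)) {
        ll <- ll + lgamma(u[i] + a) + lgamma(v[i] + b) -
          lgamma(u[i] + v[i] + a + b) - lb0
      }
    }
    j <- which.max(ll)
    if (ll[j] > best["ll"]) best <- c(ll = ll[j] + const, Pi = pis[j], phi = phi)
  }
  best
}
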