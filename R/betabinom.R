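# Beta-binomial likelihood for a paired count conditional on the pair total.
#
# Parameterisation: the expected proportion of reads in the first member is
# Pi; after library-scaling correction the effective proportion is
# p = Pi*L / (Pi*L + (1 - Pi)*L'). With dispersion phi in [0, 1) the beta
# shapes are alpha = p(1-phi)/phi and beta = (1-p)(1-phi)/phi; phi = 0 is
# exactly the binomial.

PHI_MAX <- 1 - 1e-6
# below this the beta shapes exceed ~1e9 and the log-gamma differences lose
# precision; the distribution is numerically binomial there anyway
PHI_MIN <- 1e-9

#' Effective proportion after library-scaling correction
#'
#' @param Pi Expected proportion of reads in the first member of a pair,
#'   before scaling correction; in (0, 1).
#' @param L,L_prime Library scaling factors of the first/second member;
#'   strictly positive.
#' @return `p = Pi * L / (Pi * L + (1 - Pi) * L_prime)`; equals `Pi` when
#'   the factors agree.
#' @examples
#' effective_proportion(0.5, 2, 1) # 2/3
#' @export
effective_proportion <- function(Pi, L, L_prime) {
  if (any(Pi <= 0) || any(Pi >= 1)) abort("`Pi` must lie strictly inside (0, 1).")
  if (any(L <= 0) || any(L_prime <= 0)) abort("scaling factors must be positive.")
  Pi * L / (Pi * L + (1 - Pi) * L_prime)
}

#' Log-probability of a paired count under the (beta-)binomial model
#'
#' Conditional on the pair total `N = u + u_prime`, `u` is beta-binomial
#' with effective proportion `p` (see [effective_proportion()]) and
#' dispersion `phi`:
#' `P = choose(N, u) * B(u + alpha, u' + beta) / B(alpha, beta)` for
#' `phi > 0`, and the binomial pmf at `phi = 0`. Computed in log space via
#' log-gamma so pair totals of 1e5 and more remain finite.
#'
#' Vectorised over `u`, `u_prime` (and `Pi`, `L`, `L_prime` by recycling);
#' `phi` must be a scalar. `phi` is clamped to `[0, 1 - 1e-6]` before the
#' beta shapes are formed, and dispersions below `1e-9` take the binomial
#' branch: the two are numerically indistinguishable there, while the beta
#' shapes would overflow the precision of the log-gamma differences.
#'
#' @param u,u_prime Non-negative integer counts.
#' @param Pi Expected proportion in (0, 1).
#' @param phi Dispersion in `[0, 1)`.
#' @param L,L_prime Library scaling factors.
#' @return Log-probabilities, same length as `u`.
#' @examples
#' log_betabinom_pair(1, 1, 0.5, 0) # log(0.5)
#' @export
log_betabinom_pair <- function(u, u_prime, Pi, phi, L = 1, L_prime = 1) {
  if (length(phi) != 1L) abort("`phi` must be a single value.")
  if (is.na(phi) || phi < 0 || phi >= 1) abort("`phi` must lie in [0, 1).")
  if (any(u < 0) || any(u_prime < 0)) abort("negative count.")
  phi <- min(phi, PHI_MAX)
  p <- effective_proportion(Pi, L, L_prime)
  N <- u + u_prime
  lc <- lchoose(N, u)
  if (phi < PHI_MIN) {
    lc + u * log(p) + u_prime * log1p(-p)
  } else {
    a <- p * (1 - phi) / phi
    b <- (1 - p) * (1 - phi) / phi
    lc + lbeta(u + a, u_prime + b) - lbeta(a, b)
  }
}

#' Variance of the paired count under the beta-binomial model
#'
#' `Var(u) = N * p * (1 - p) * (1 + (N - 1) * phi)` for pair total `N`;
#' `phi = 0` recovers the binomial variance, and at fixed `N` and `p` the
#' extra variance scales linearly in `phi`.
#'
#' @param N Pair total `u + u_prime` (non-negative).
#' @param p Effective proportion.
#' @param phi Dispersion in `[0, 1]`.
#' @return The variance.
#' @export
pair_variance <- function(N, p, phi) {
  if (any(N < 0)) abort("`N` must be non-negative.")
  if (any(phi < 0) || any(phi > 1)) abort("`phi` must lie in [0, 1].")
  N * p * (1 - p) * (1 + (N - 1) * phi)
}
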