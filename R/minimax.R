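# The Kumaraswamy ("minimax") distribution on (0, 1):
# f(x) = alpha * beta * x^(alpha - 1) * (1 - x^alpha)^(beta - 1),
# used as an alternative biological-noise family in the simulator. Raw
# moments are E(X^r) = beta * B(1 + r/alpha, beta); there is no closed form
# for the parameters in terms of mean and variance, so they are solved
# numerically.

#' Kumaraswamy (minimax) distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the two-parameter minimax distribution on (0, 1). Sampling uses the
#' exact inverse CDF `x = (1 - (1 - v)^(1/beta))^(1/alpha)`.
#'
#' @param x,q Quantiles in (0, 1).
#' @param p Probabilities.
#' @param n Number of draws.
#' @param alpha,beta Positive shape parameters.
#' @return Numeric vector.
#' @name minimax
NULL

#' @rdname minimax
#' @export
dminimax <- function(x, alpha, beta) {
  out <- numeric(length(x))
  ok <- x > 0 & x < 1
  out[ok] <- alpha * beta * x[ok]^(alpha - 1) * (1 - x[ok]^alpha)^(beta - 1)
  out
}

#' @rdname minimax
#' @export
pminimax <- function(q, alpha, beta) {
  q <- pmin(pmax(q, 0), 1)
  1 - (1 - q^alpha)^beta
}

#' @rdname minimax
#' @export
qminimax <- function(p, alpha, beta) {
  (1 - (1 - p)^(1 / beta))^(1 / alpha)
}

#' @rdname minimax
#' @export
rminimax <- function(n, alpha, beta) {
  qminimax(runif(n), alpha, beta)
}

#' Raw moment of the minimax distribution
#'
#' `E(X^r) = beta * B(1 + r/alpha, beta)`.
#'
#' @param r Moment order.
#' @param alpha,beta Shape parameters.
#' @return The raw moment.
#' @export
minimax_moment <- function(r, alpha, beta) {
  beta * exp(lbeta(1 + r / alpha, beta))
}

#' Solve minimax parameters matching a target mean and variance
#'
#' Finds `(alpha, beta)` such that the minimax mean and variance equal the
#' targets, by nested root-finding: for a trial `alpha`, `beta` is solved
#' from the mean (which is strictly decreasing in `beta`), then `alpha` is
#' solved from the variance. A moment pair is feasible only when
#' `0 < variance < mean * (1 - mean)`.
#'
#' @param target_mean Desired mean in (0, 1).
#' @param target_variance Desired variance.
#' @param tol Root-finding tolerance (on the moments).
#' @return A list with `alpha`, `beta` and the achieved `mean`, `variance`.
#' @examples
#' solve_minimax_parameters(0.5, 1 / 12) # alpha = beta = 1 (uniform)
#' @export
solve_minimax_parameters <- function(target_mean, target_variance, tol = 1e-12) {
  m <- target_mean
  v <- target_variance
  if (m <= 0 || m >= 1) abort("`target_mean` must lie in (0, 1).")
  if (v <= 0 || v >= m * (1 - m)) {
    abort("infeasible moment pair: need 0 < variance < mean * (1 - mean).")
  }

  # the mean is strictly decreasing in beta; for large alpha the matching
  # beta is enormous, so the inner search runs on a wide log scale
  beta_for_mean <- function(alpha) {
    f <- function(lb) minimax_moment(1, alpha, exp(lb)) - m
    lo <- -300; hi <- 690
    flo <- f(lo); fhi <- f(hi)
    if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) return(NA_real_)
    exp(uniroot(f, c(lo, hi), tol = tol)$root)
  }
  var_gap <- function(la) {
    alpha <- exp(la)
    beta <- beta_for_mean(alpha)
    if (!is.finite(beta)) return(NA_real_)
    minimax_moment(2, alpha, beta) - m^2 - v
  }

  # the variance decreases monotonically in alpha but the moment equations
  # are only evaluable on a finite log-alpha window (they saturate at both
  # extremes), so scan coarsely for a sign change and refine with uniroot
  las <- seq(-32, 32, by = 2)
  gaps <- vapply(las, var_gap, numeric(1))
  fin <- which(is.finite(gaps))
  bracket <- NULL
  for (j in fin[-length(fin)]) {
    if (!is.finite(gaps[j + 1L])) next
    if (gaps[j] == 0) { bracket <- c(las[j], las[j]); break }
    if (gaps[j] * gaps[j + 1L] < 0) { bracket <- c(las[j], las[j + 1L]); break }
  }
  if (is.null(bracket)) {
    abort("minimax solver failed to bracket the target variance (moments too extreme).")
  }
  la <- if (bracket[1] == bracket[2]) bracket[1] else {
    uniroot(var_gap, bracket, tol = tol)$root
  }
  alpha <- exp(la)
  beta <- beta_for_mean(alpha)
  list(
    alpha = alpha, beta = beta,
    mean = minimax_moment(1, alpha, beta),
    variance = minimax_moment(2, alpha, beta) - minimax_moment(1, alpha, beta)^2
  )
}
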