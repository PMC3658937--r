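# Marginal likelihoods, BIC-based priors, posterior model probabilities
# and FDR estimation from posteriors.

#' Approximate marginal log-likelihood of a model for every tuple
#'
#' The marginal likelihood factorises over the model sets; within each set
#' the integral over the parameter distribution is approximated by the mean,
#' over the empirical sample `Theta_q`, of the within-set likelihood
#' product:
#' `P(D_c | M) ~ prod_q (1/|Theta_q|) sum_{zeta in Theta_q}
#'  prod_{i in E_q} P((u_ic, u'_ic) | zeta)`.
#' The mean is computed by log-sum-exp, so the result is deterministic given
#' `theta` and finite even for large pair totals.
#'
#' @param data A `pbb_counts` table (all tuples are evaluated).
#' @param model A `pbb_model`.
#' @param theta A `pbb_theta` built for this model (see [build_theta()]).
#' @param scaling Optional `pbb_scaling` table.
#' @return Numeric vector of log marginal likelihoods, one per tuple.
#' @export
marginal_log_likelihood <- function(data, model, theta, scaling = NULL) {
  data <- as_paired_counts(data)
  n <- length(pair_labels(data))
  sc <- scaling %||% scaling_factors(rep(1, n), rep(1, n), pair_labels(data))
  if (length(theta) != length(model$sets)) {
    abort("`theta` does not match the model's sets.")
  }
  U <- counts_first(data)
  V <- counts_second(data)
  C <- nrow(U)
  # the multinomial coefficients are parameter-free; since the sets
  # partition the pairs, they contribute one per-tuple constant
  total <- unname(rowSums(lchoose(U + V, U)))
  for (q in seq_along(model$sets)) {
    th <- theta[[q]]
    K <- nrow(th)
    if (K == 0L) abort("empty Theta sample for a model set.")
    idx <- model$sets[[q]]
    acc <- matrix(0, C, K)
    for (k in seq_len(K)) {
      phi_k <- min(max(th$phi[k], 0), PHI_MAX)
      ll <- numeric(C)
      for (i in idx) {
        p <- effective_proportion(th$Pi[k], sc$L[i], sc$L_prime[i])
        ll <- ll + lbb_kernel(U[, i], V[, i], p, phi_k)
      }
      acc[, k] <- ll
    }
    total <- total + row_logsumexp(acc) - log(K)
  }
  total
}

#' Estimate model priors by BIC assignment
#'
#' Each tuple is assigned to the model minimising
#' `BIC_M = -2 log P(D_c | M) + k_M log(n_pairs)`, where `k_M` counts the
#' FREE proportion sets of the model (the dispersion is shared by all models
#' and therefore not counted). The priors are the assignment proportions,
#' floored at `floor` and renormalised so no model has exactly zero prior.
#' Ties go to the model with fewer FREE sets.
#'
#' @param loglik Matrix of log marginal likelihoods (tuples x models).
#' @param models List of `pbb_model` objects (one per column).
#' @param n_pairs Number of sample pairs (the BIC observation count).
#' @param floor Minimum prior before renormalisation.
#' @param exclude Logical vector flagging tuples to drop from the
#'   assignment counts (e.g. all-zero tuples, uninformative under every
#'   model).
#' @return Named numeric vector of priors summing to one.
#' @export
estimate_priors_bic <- function(loglik, models, n_pairs, floor = 1e-3,
                                exclude = NULL) {
  loglik <- as.matrix(loglik)
  M <- length(models)
  if (ncol(loglik) != M) abort("`loglik` must have one column per model.")
  k <- vapply(models, n_free_sets, numeric(1))
  bic <- -2 * loglik + matrix(k * log(n_pairs), nrow(loglik), M, byrow = TRUE)
  if (!is.null(exclude) && any(exclude)) bic <- bic[!exclude, , drop = FALSE]
  nm <- vapply(models, function(m) m$name, character(1))
  if (nrow(bic) == 0L) {
    return(setNames(rep(1 / M, M), nm))
  }
  # break ties toward fewer FREE sets: evaluate columns in order of parsimony
  ord <- order(k)
  pick_sorted <- max.col(-bic[, ord, drop = FALSE], ties.method = "first")
  pick <- ord[pick_sorted]
  prop <- tabulate(pick, nbins = M) / nrow(bic)
  prior <- pmax(prop, floor)
  prior <- prior / sum(prior)
  setNames(prior, nm)
}

#' Posterior model probabilities from log-likelihoods and priors
#'
#' Bayes' rule on each tuple's row: posteriors are proportional to
#' `exp(loglik) * prior`, normalised by the summed evidence over the finite
#' model set (computed by log-sum-exp).
#'
#' @param loglik Numeric vector (one tuple) or matrix (tuples x models) of
#'   log marginal likelihoods.
#' @param priors Model priors summing to one.
#' @return Posterior probabilities, same shape as `loglik`; each row sums
#'   to one.
#' @export
posterior_probabilities <- function(loglik, priors) {
  vec <- !is.matrix(loglik)
  loglik <- as.matrix(if (vec) matrix(loglik, nrow = 1L) else loglik)
  if (length(priors) != ncol(loglik)) abort("one prior per model is required.")
  if (abs(sum(priors) - 1) > 1e-8) abort("`priors` must sum to 1.")
  lp <- sweep(loglik, 2L, log(priors), `+`)
  denom <- row_logsumexp(lp)
  if (any(!is.finite(denom))) abort("all model likelihoods vanished for some tuple.")
  post <- exp(lp - denom)
  dimnames(post) <- dimnames(loglik)
  if (vec) drop(post) else post
}

#' Estimate false discovery rates from posterior probabilities
#'
#' If the posterior probability that model `M` holds for tuple `c` is
#' `p_cM`, the probability that a call of `M` on `c` is false is
#' `1 - p_cM`. Ranking tuples by decreasing posterior, the FDR among the
#' top `m` calls is estimated as the mean of `1 - p_cM` over those calls.
#' Ties in the posterior are ordered by tuple id for reproducibility.
#'
#' @param posterior Per-tuple posterior probabilities for one model.
#' @param tuple_id Optional identifiers (used for tie-breaking and output).
#' @return A tibble in input order with columns `tuple_id`, `posterior`,
#'   `rank` (position in the ranked list) and `fdr` (cumulative estimate at
#'   that rank); `fdr` is non-decreasing down the ranked list.
#' @export
estimate_fdr <- function(posterior, tuple_id = NULL) {
  if (any(posterior < 0 | posterior > 1)) abort("posteriors must lie in [0, 1].")
  ids <- tuple_id %||% paste0("t", seq_along(posterior))
  ord <- order(-posterior, ids)
  fdr_sorted <- cumsum(1 - posterior[ord]) / seq_along(ord)
  rank <- integer(length(posterior))
  rank[ord] <- seq_along(ord)
  tibble::tibble(
    tuple_id = as.character(ids),
    posterior = as.numeric(posterior),
    rank = rank,
    fdr = fdr_sorted[rank]
  )
}

#' Select tuples at a target false discovery rate
#'
#' Takes the largest prefix of the posterior-ranked list whose estimated
#' FDR does not exceed the threshold.
#'
#' @param fdr A tibble from [estimate_fdr()] (or a posterior vector, which
#'   is passed through it).
#' @param threshold Target FDR in `[0, 1)`.
#' @return Character vector of selected tuple ids (ranked order).
#' @export
select_at_fdr <- function(fdr, threshold = 0.05) {
  if (threshold < 0 || threshold >= 1) abort("`threshold` must lie in [0, 1).")
  if (!is.data.frame(fdr)) fdr <- estimate_fdr(fdr)
  ok <- fdr$rank[fdr$fdr <= threshold]
  if (length(ok) == 0L) return(character(0))
  m <- max(ok)
  fdr$tuple_id[order(fdr$rank)][seq_len(m)]
}
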