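# End-to-end posterior analysis: Theta construction, marginal likelihoods,
# BIC priors, posteriors and FDR for every model.

#' Posterior model probabilities for paired count data
#'
#' Runs the full empirical Bayesian analysis: validates the design, builds
#' the empirical parameter sample for each model ([build_theta()]),
#' approximates the marginal log-likelihoods ([marginal_log_likelihood()]),
#' estimates model priors by BIC assignment ([estimate_priors_bic()]) and
#' computes posterior probabilities and FDRs per model. All-zero tuples have
#' likelihood one under every model; they are excluded from the BIC
#' assignment counts and receive equal posteriors across the models.
#'
#' @param data A `pbb_counts` table (or wide data frame).
#' @param models List of `pbb_model` objects; defaults to
#'   [default_models()] on the replicate-group labels when `reps` has at
#'   most two groups.
#' @param reps Replicate structure.
#' @param scaling A `pbb_scaling` table; defaults to total-count factors
#'   ([estimate_scaling_factors()]).
#' @param theta_size Tuples sampled per model for the parameter sample;
#'   default `min(5000, n eligible)`.
#' @param seed Integer seed for the Theta tuple sample.
#' @param per_group_dispersion Passed to [build_theta()].
#' @param priors Optional fixed prior vector overriding BIC estimation.
#' @return An object of class `pbb_fit`; see [tidy.pbb_fit()],
#'   [glance.pbb_fit()], [autoplot.pbb_fit()].
#' @examples
#' sim <- simulate_dataset(n_tuples = 200, n_within_de = 20, n_pairs = 4,
#'                         b = 2, seed = 7)
#' fit <- pbb_posterior(sim$counts, reps = rep("R", 4), scaling = sim$scaling,
#'                      theta_size = 25, seed = 7)
#' head(tidy(fit))
#' @export
pbb_posterior <- function(data, models = NULL, reps, scaling = NULL,
                          theta_size = NULL, seed = 1L,
                          per_group_dispersion = FALSE, priors = NULL) {
  data <- as_paired_counts(data)
  n <- length(pair_labels(data))
  reps <- replicate_structure(reps, n_pairs = n)
  if (is.null(models)) {
    cond <- rep(names(reps), lengths(reps))[order(unlist(reps))]
    models <- if (length(reps) == 2L) default_models(n, cond) else default_models(n)
  }
  sc <- scaling %||% estimate_scaling_factors(data)
  design <- validate_design(data, sc, reps, models)

  thetas <- lapply(models, function(m) {
    build_theta(data, m, reps, sc,
      sample_size = theta_size, seed = seed,
      per_group_dispersion = per_group_dispersion
    )
  })
  loglik <- vapply(
    seq_along(models),
    function(j) marginal_log_likelihood(data, models[[j]], thetas[[j]], sc),
    numeric(nrow(data))
  )
  loglik <- matrix(loglik, nrow = nrow(data))
  nm <- vapply(models, function(m) m$name, character(1))
  dimnames(loglik) <- list(data$tuple_id, nm)

  zero <- all_zero_tuples(data)
  if (is.null(priors)) {
    priors <- estimate_priors_bic(loglik, models, n_pairs = n, exclude = zero)
  } else {
    if (length(priors) != length(models)) abort("one prior per model is required.")
    priors <- setNames(priors / sum(priors), nm)
  }
  post <- posterior_probabilities(loglik, priors)
  if (any(zero)) post[zero, ] <- 1 / length(models)

  fdr <- lapply(nm, function(m) estimate_fdr(post[, m], data$tuple_id))
  names(fdr) <- nm

  structure(
    list(
      tuple_id = data$tuple_id, models = models, theta = thetas,
      loglik = loglik, priors = priors, posterior = post, fdr = fdr,
      all_zero = zero, n_pairs = n, seed = seed,
      theta_size = nrow(thetas[[1]][[1]]),
      per_group_dispersion = per_group_dispersion
    ),
    class = "pbb_fit"
  )
}

#' @export
print.pbb_fit <- function(x, ...) {
  cat("Paired beta-binomial posterior fit\n")
  cat("  tuples:", length(x$tuple_id), " sample pairs:", x$n_pairs,
    " Theta size:", x$theta_size, "\n"
  )
  cat("  priors:\n")
  for (m in names(x$priors)) cat(sprintf("    %-20s %.4f\n", m, x$priors[m]))
  invisible(x)
}

#' Tidy a posterior fit into one row per tuple and model
#'
#' @param x A `pbb_fit`.
#' @param ... Unused.
#' @return A tibble with columns `tuple_id`, `model`, `log_likelihood`,
#'   `posterior`, `rank`, `fdr`.
#' @export
tidy.pbb_fit <- function(x, ...) {
  nm <- colnames(x$posterior)
  purrr::map_dfr(nm, function(m) {
    tibble::tibble(
      tuple_id = x$tuple_id,
      model = m,
      log_likelihood = x$loglik[, m],
      posterior = x$posterior[, m],
      rank = x$fdr[[m]]$rank,
      fdr = x$fdr[[m]]$fdr
    )
  })
}

#' One-row summary of a posterior fit
#'
#' @param x A `pbb_fit`.
#' @param ... Unused.
#' @return A tibble with tuple/pair/model counts, Theta sample size, seed
#'   and one `prior_<model>` column per model.
#' @export
glance.pbb_fit <- function(x, ...) {
  out <- tibble::tibble(
    n_tuples = length(x$tuple_id),
    n_pairs = x$n_pairs,
    n_models = length(x$models),
    theta_size = x$theta_size,
    n_all_zero = sum(x$all_zero),
    seed = x$seed
  )
  for (m in names(x$priors)) out[[paste0("prior_", m)]] <- unname(x$priors[m])
  out
}

#' Plot ranked posterior and FDR curves of a fit
#'
#' One panel per model: tuples ranked by decreasing posterior probability,
#' the posterior (solid) and the cumulative FDR estimate (dashed) against
#' rank.
#'
#' @param object A `pbb_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pbb_fit <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("posterior", "fdr"),
      names_to = "quantity", values_to = "value"
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$rank, y = .data$value, linetype = .data$quantity
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "rank (by posterior)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Extract the wide posterior table
#'
#' @param fit A `pbb_fit`.
#' @return A tibble: `tuple_id`, then `loglik_<model>`,
#'   `posterior_<model>`, `fdr_<model>` per model.
#' @export
posterior_table <- function(fit) {
  out <- tibble::tibble(tuple_id = fit$tuple_id)
  for (m in colnames(fit$posterior)) {
    out[[paste0("loglik_", m)]] <- fit$loglik[, m]
    out[[paste0("posterior_", m)]] <- fit$posterior[, m]
    out[[paste0("fdr_", m)]] <- fit$fdr[[m]]$fdr
  }
  out
}
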