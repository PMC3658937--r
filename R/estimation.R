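# Maximum-likelihood estimation of per-tuple proportions and dispersion
# under the replicate structure, and construction of the empirical
# parameter samples used as discrete priors.

PI_EPS <- 1e-6

clamp_pi <- function(x) pmin(pmax(x, PI_EPS), 1 - PI_EPS)

# Joint log-likelihood of one tuple under the replicate structure: product
# over replicate groups r and pairs i in F_r of the pair pmf at (Pi_r, phi).
replicate_loglik <- function(u, u_prime, sets, Pis, phi, L, L_prime) {
  ll <- 0
  for (r in seq_along(sets)) {
    i <- sets[[r]]
    ll <- ll + sum(log_betabinom_pair(u[i], u_prime[i], Pis[r], phi, L[i], L_prime[i]))
  }
  ll
}

# Hot-loop variant of the pair log-pmf without the multinomial coefficient
# (constant in the parameters) or argument checking; vectorised over pairs.
lbb_kernel <- function(u, u_prime, p, phi) {
  if (phi < PHI_MIN) {
    u * log(p) + u_prime * log1p(-p)
  } else {
    a <- p * (1 - phi) / phi
    b <- (1 - p) * (1 - phi) / phi
    lbeta(u + a, u_prime + b) - lbeta(a, b)
  }
}

#' Estimate the dispersion of one tuple pair under the replicate structure
#'
#' Jointly maximises the likelihood of the paired counts over a shared
#' dispersion `phi` and one expected proportion `Pi_r` per replicate group.
#' Optimisation runs on logit-transformed parameters with multiple starts
#' (method-of-moments and 0.5 for the proportions; dispersion starts at
#' 1e-4, 0.05 and 0.3) and also evaluates the exact `phi = 0` binomial
#' boundary, keeping the best solution.
#'
#' @param u,u_prime Counts for one tuple across the sample pairs.
#' @param reps Replicate structure (see [replicate_structure()]).
#' @param L,L_prime Library scaling factors (default 1).
#' @param restrict_to Optional index set of sample pairs; only these pairs
#'   (and the replicate structure induced on them) contribute.
#' @return A list of class `pbb_dispersion_fit`: `phi`, named vector `Pi`
#'   (one per retained replicate group), `loglik`, `converged`,
#'   `degenerate`. A tuple whose retained pair totals are all zero is
#'   flagged degenerate and reported as `phi = 0`, `Pi = 0.5`.
#' @seealso [estimate_proportion()], [build_theta()]
#' @export
estimate_dispersion <- function(u, u_prime, reps, L = 1, L_prime = 1,
                                restrict_to = NULL) {
  n <- length(u)
  reps <- replicate_structure(reps, n_pairs = n)
  L <- rep_len(L, n)
  L_prime <- rep_len(L_prime, n)
  sets <- unclass(reps)
  attributes(sets) <- list(names = names(reps))
  if (!is.null(restrict_to)) {
    keep <- as.integer(restrict_to)
    sets <- lapply(sets, function(s) intersect(s, keep))
    sets <- sets[lengths(sets) > 0L]
    if (length(sets) == 0L) abort("`restrict_to` leaves no sample pairs.")
  }

  N <- u + u_prime
  informative <- vapply(sets, function(s) any(N[s] > 0), logical(1))
  if (!any(informative)) {
    return(structure(
      list(
        phi = 0, Pi = setNames(rep(0.5, length(sets)), names(sets)),
        loglik = 0, converged = TRUE, degenerate = TRUE
      ),
      class = "pbb_dispersion_fit"
    ))
  }
  act <- sets[informative]
  s <- length(act)

  # flatten to per-pair vectors; pairs with zero totals contribute a
  # constant (probability one) and are dropped from the objective
  pidx <- unlist(act, use.names = FALSE)
  pidx <- pidx[N[pidx] > 0]
  grp <- rep(seq_along(act), vapply(act, function(i) sum(N[i] > 0), integer(1)))
  uu <- u[pidx]; vv <- u_prime[pidx]
  LL <- L[pidx]; LLp <- L_prime[pidx]
  const <- sum(lchoose(uu + vv, uu))

  obj <- function(Pis, phi) {
    p <- Pis[grp] * LL / (Pis[grp] * LL + (1 - Pis[grp]) * LLp)
    sum(lbb_kernel(uu, vv, p, phi))
  }

  # phi = 0 boundary: independent binomial profile per group
  pi0 <- vapply(seq_len(s), function(r) {
    sel <- grp == r
    prof <- function(Pi) {
      p <- Pi * LL[sel] / (Pi * LL[sel] + (1 - Pi) * LLp[sel])
      sum(uu[sel] * log(p) + vv[sel] * log1p(-p))
    }
    opt <- optimize(prof, interval = c(PI_EPS, 1 - PI_EPS), maximum = TRUE, tol = 1e-10)
    cand <- clamp_pi(c(opt$maximum, PI_EPS, 1 - PI_EPS))
    cand[which.max(vapply(cand, prof, numeric(1)))]
  }, numeric(1))
  best <- list(Pi = pi0, phi = 0, loglik = obj(pi0, 0), converged = TRUE)

  # interior optimisation on (qlogis(Pi_1..s), qlogis(phi))
  negll <- function(par) {
    Pis <- clamp_pi(plogis(par[seq_len(s)]))
    phi <- min(plogis(par[s + 1L]), PHI_MAX)
    -obj(Pis, phi)
  }
  # analytic gradient: both beta shapes share the total T = (1 - phi)/phi,
  # so the phi-derivative reduces to a single digamma sum; Pi enters only
  # through the effective proportion p
  negll_grad <- function(par) {
    Pis <- clamp_pi(plogis(par[seq_len(s)]))
    phi <- min(plogis(par[s + 1L]), PHI_MAX)
    Pig <- Pis[grp]
    den <- Pig * LL + (1 - Pig) * LLp
    p <- Pig * LL / den
    dp_dPi <- LL * LLp / den^2
    if (phi < PHI_MIN) {
      dll_dp <- uu / p - vv / (1 - p)
      gx <- rowsum(dll_dp * dp_dPi, grp)[, 1] * Pis * (1 - Pis)
      return(-c(gx, 0))
    }
    Tt <- (1 - phi) / phi
    a <- p * Tt
    b <- (1 - p) * Tt
    da <- digamma(uu + a) - digamma(a)
    db <- digamma(vv + b) - digamma(b)
    dll_dp <- Tt * (da - db)
    gx <- rowsum(dll_dp * dp_dPi, grp)[, 1] * Pis * (1 - Pis)
    dll_dT <- sum(p * da + (1 - p) * db) +
      length(uu) * digamma(Tt) - sum(digamma(uu + vv + Tt))
    # chain rule on the logit scale: dT/dy = -T
    -c(gx, dll_dT * (-Tt))
  }
  mom <- vapply(seq_len(s), function(r) {
    sel <- grp == r
    num <- sum(uu[sel] / LL[sel])
    den <- num + sum(vv[sel] / LLp[sel])
    if (den == 0) 0.5 else clamp_pi(num / den)
  }, numeric(1))
  for (pi_s in list(mom, rep(0.5, s))) {
    for (phi_s in c(1e-4, 0.05, 0.3)) {
      fit <- tryCatch(
        optim(c(qlogis(pi_s), qlogis(phi_s)), negll, gr = negll_grad,
          method = "BFGS", control = list(maxit = 200, reltol = 1e-10)
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      ll <- -fit$value
      if (is.finite(ll) && ll > best$loglik + 1e-12) {
        best <- list(
          Pi = clamp_pi(plogis(fit$par[seq_len(s)])),
          phi = min(plogis(fit$par[s + 1L]), PHI_MAX),
          loglik = ll, converged = fit$convergence == 0
        )
      }
    }
  }
  best$loglik <- best$loglik + const

  if (best$phi < PHI_MIN) best$phi <- 0
  Pi_full <- setNames(rep(0.5, length(sets)), names(sets))
  Pi_full[names(act)] <- best$Pi
  structure(
    list(
      phi = best$phi, Pi = Pi_full, loglik = best$loglik,
      converged = best$converged, degenerate = FALSE
    ),
    class = "pbb_dispersion_fit"
  )
}

#' Estimate the expected proportion of one model set at fixed dispersion
#'
#' One-dimensional profile maximum-likelihood for `Pi` over the sample pairs
#' in a model set, holding the dispersion at the value obtained under the
#' replicate structure. The estimate is clamped to `[1e-6, 1 - 1e-6]` so
#' that boundary maximisers keep the beta shapes finite downstream.
#'
#' @param u,u_prime Counts for the pairs in the set.
#' @param phi Fixed dispersion.
#' @param L,L_prime Scaling factors for those pairs.
#' @return The clamped maximiser.
#' @export
estimate_proportion <- function(u, u_prime, phi, L = 1, L_prime = 1) {
  if (length(u) == 0L) abort("empty set: no sample pairs to estimate from.")
  n <- length(u)
  L <- rep_len(L, n)
  L_prime <- rep_len(L_prime, n)
  ll <- function(Pi) sum(log_betabinom_pair(u, u_prime, Pi, phi, L, L_prime))
  opt <- optimize(ll, interval = c(PI_EPS, 1 - PI_EPS), maximum = TRUE, tol = 1e-10)
  cand <- c(opt$maximum, PI_EPS, 1 - PI_EPS)
  cand[which.max(vapply(cand, ll, numeric(1)))]
}

#' Fit per-tuple dispersion and group proportions for a whole count table
#'
#' Applies [estimate_dispersion()] to each requested tuple and returns a
#' tidy table, suitable for caching (see [run_pipeline()]).
#'
#' @param data A `pbb_counts` table.
#' @param reps Replicate structure.
#' @param scaling A `pbb_scaling` table (defaults to unit factors).
#' @param tuples Optional subset of tuple ids or indices.
#' @return A tibble with `tuple_id`, `phi`, `loglik`, `converged`,
#'   `degenerate` and one `Pi_<group>` column per replicate group.
#' @export
fit_dispersion <- function(data, reps, scaling = NULL, tuples = NULL) {
  data <- as_paired_counts(data)
  n <- length(pair_labels(data))
  reps <- replicate_structure(reps, n_pairs = n)
  sc <- scaling %||% scaling_factors(rep(1, n), rep(1, n), pair_labels(data))
  U <- counts_first(data)
  V <- counts_second(data)
  idx <- seq_len(nrow(data))
  if (!is.null(tuples)) {
    idx <- if (is.character(tuples)) match(tuples, data$tuple_id) else as.integer(tuples)
  }
  fits <- lapply(idx, function(i) {
    estimate_dispersion(U[i, ], V[i, ], reps, sc$L, sc$L_prime)
  })
  out <- tibble::tibble(
    tuple_id = data$tuple_id[idx],
    phi = vapply(fits, `[[`, numeric(1), "phi"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    degenerate = vapply(fits, `[[`, logical(1), "degenerate")
  )
  for (g in names(reps)) {
    out[[paste0("Pi_", g)]] <- vapply(fits, function(f) unname(f$Pi[g]), numeric(1))
  }
  out
}

#' Build the empirical parameter sample for a model
#'
#' For each set `E_q` of the model, draws `sample_size` tuples uniformly
#' without replacement among eligible tuples and records one `(Pi, phi)`
#' pair per sampled tuple: `phi` from the replicate-structure fit and, for
#' FREE sets, `Pi` from the profile fit over `E_q`; FIXED sets carry their
#' constant proportion. The same sampled tuples (and shared `phi`) are used
#' across all sets of the model. A tuple is eligible when every replicate
#' group contains at least one pair with a positive pair total; all-zero
#' tuples are never sampled.
#'
#' @param data A `pbb_counts` table.
#' @param model A `pbb_model`.
#' @param reps Replicate structure.
#' @param scaling Optional `pbb_scaling` table.
#' @param sample_size Number of tuples to sample; default
#'   `min(5000, n eligible)`. When it exceeds the eligible count all
#'   eligible tuples are used (with a notice).
#' @param seed Integer seed controlling the tuple sample.
#' @param per_group_dispersion When `TRUE`, the dispersion entering a FREE
#'   set is re-estimated from that set's pairs only (with the induced
#'   replicate structure) instead of shared across sets. Default `FALSE`,
#'   appropriate for small numbers of samples.
#' @return An object of class `pbb_theta`: a list with one tibble
#'   (columns `Pi`, `phi`) per model set, attributes `tuple_ids`, `seed`,
#'   `model`.
#' @export
build_theta <- function(data, model, reps, scaling = NULL, sample_size = NULL,
                        seed = 1L, per_group_dispersion = FALSE) {
  data <- as_paired_counts(data)
  n <- length(pair_labels(data))
  reps <- replicate_structure(reps, n_pairs = n)
  sc <- scaling %||% scaling_factors(rep(1, n), rep(1, n), pair_labels(data))
  U <- counts_first(data)
  V <- counts_second(data)
  N <- U + V

  eligible <- rep(TRUE, nrow(data))
  for (g in seq_along(reps)) {
    i <- reps[[g]]
    eligible <- eligible & (rowSums(N[, i, drop = FALSE] > 0) > 0)
  }
  n_elig <- sum(eligible)
  if (n_elig == 0L) abort("no eligible tuples: every replicate group is all-zero everywhere.")
  if (is.null(sample_size)) sample_size <- min(5000L, n_elig)
  if (sample_size > n_elig) {
    inform(paste0(
      "sample_size (", sample_size, ") exceeds eligible tuples (",
      n_elig, "); using all eligible tuples."
    ))
    sample_size <- n_elig
  }
  pool <- which(eligible)
  take <- with_seed(seed, function() sort(sample(pool, sample_size)))

  n_sets <- length(model$sets)
  Pi_mat <- matrix(NA_real_, sample_size, n_sets)
  Phi_mat <- matrix(NA_real_, sample_size, n_sets)
  for (j in seq_along(take)) {
    i <- take[j]
    fit <- estimate_dispersion(U[i, ], V[i, ], reps, sc$L, sc$L_prime)
    for (q in seq_len(n_sets)) {
      Eq <- model$sets[[q]]
      phi_q <- fit$phi
      if (per_group_dispersion) {
        phi_q <- estimate_dispersion(U[i, ], V[i, ], reps, sc$L, sc$L_prime,
          restrict_to = Eq
        )$phi
      }
      Phi_mat[j, q] <- phi_q
      Pi_mat[j, q] <- if (!is.na(model$fixed[q])) {
        model$fixed[q]
      } else {
        estimate_proportion(U[i, Eq], V[i, Eq], phi_q, sc$L[Eq], sc$L_prime[Eq])
      }
    }
  }
  out <- lapply(seq_len(n_sets), function(q) {
    tibble::tibble(Pi = Pi_mat[, q], phi = Phi_mat[, q])
  })
  structure(out,
    tuple_ids = data$tuple_id[take], seed = seed, model = model$name,
    per_group_dispersion = per_group_dispersion, class = "pbb_theta"
  )
}

#' @export
print.pbb_theta <- function(x, ...) {
  cat(
    "Empirical parameter sample for model", attr(x, "model"), "-",
    length(x), "set(s) x", nrow(x[[1]]), "sampled tuples\n"
  )
  invisible(x)
}
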