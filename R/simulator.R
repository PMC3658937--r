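# Simulator for paired count data: independent Poisson counts whose means
# mix a baseline rate, library scaling, individual effects and a biological
# noise proportion drawn from a beta (or moment-matched Kumaraswamy)
# distribution. Produces full truth labels for benchmarking.

LAMBDA_LOG10_MEAN <- -3.3
LAMBDA_LOG10_SD <- 0.8
LAMBDA_LOG10_RANGE <- c(-6, -1)

# map standard uniforms to the truncated log-normal baseline-rate pool
lambda_from_uniform <- function(u) {
  bounds <- pnorm(LAMBDA_LOG10_RANGE, LAMBDA_LOG10_MEAN, LAMBDA_LOG10_SD)
  10^qnorm(bounds[1] + u * diff(bounds), LAMBDA_LOG10_MEAN, LAMBDA_LOG10_SD)
}

#' Baseline expression-rate pool
#'
#' A reproducible heavy-tailed pool of per-tuple baseline rates: `log10`
#' rates are normal with mean -3.3 and sd 0.8, truncated to `[-6, -1]`.
#' Multiplied by library scaling factors in `[30000, 90000]` this spans
#' pair totals from below one to the thousands, the regime where count
#' discreteness matters. Drawing is one uniform per value, so for a fixed
#' seed a shorter pool is a prefix of a longer one.
#'
#' @param size Pool size.
#' @param seed Integer seed.
#' @return Positive numeric vector of rates.
#' @export
default_lambda_pool <- function(size, seed = 1L) {
  with_seed(seed, function() lambda_from_uniform(runif(size)))
}

#' Simulate a paired count dataset with truth labels
#'
#' For tuple `c` and sample pair `i`, counts are independent Poisson draws
#' with means `lambda_c * L_i * Q_ic * M_ic` and
#' `lambda_c * L'_i * Q_ic * (1 - M_ic)`. `lambda_c` is drawn from the
#' baseline pool; `L_i`, `L'_i` are uniform on `L_range`; individual
#' effects are `Q_ic = 2^nu_ic` with `nu_ic` uniform on `nu_range`; the
#' noise proportion `M_ic` is drawn from a beta distribution with shapes
#' `a_ic = mu_ic/(mu_ic + mu'_ic) * (1 - phi_c)/phi_c` (and symmetrically
#' `b_ic`), `phi_c` itself beta-distributed with shapes `phi_shape`.
#'
#' Differential expression enters through the `mu`: tuples labelled
#' `WITHIN_DE` use `mu_ic = 2^f_c`, `mu'_ic = 2^-f_c` with `f_c` uniform on
#' `[-b, b]`; tuples labelled `BETWEEN_DE` additionally scale one of the
#' two conditions by `2^(g_c)` (sign assigned by a per-tuple indicator
#' `I_c` sampled from \{0, 1\}), `g_c` uniform on `[-d, d]`. All other
#' tuples have `mu = mu' = 1`. With `noise_family = "minimax"` each beta
#' draw is replaced by a Kumaraswamy draw whose parameters are numerically
#' matched to the same mean and variance, so the two families are directly
#' comparable.
#'
#' The draw order is fixed (lambda, then L/L', phi, f, g, I, nu, M,
#' Poisson) from a single seeded generator, so a given seed reproduces the
#' dataset exactly.
#'
#' @param n_pairs Sample pairs per condition.
#' @param n_groups 1 (single condition) or 2.
#' @param n_tuples Number of tuple pairs.
#' @param n_within_de Tuples with differential expression within pairs.
#' @param n_between_de Tuples whose expression ratio also differs between
#'   the two conditions (requires `n_groups = 2`).
#' @param b,d Effect-size bounds for the within-pair and between-group
#'   log2 effects.
#' @param noise_family `"beta"` or `"minimax"`.
#' @param lambda_pool Optional numeric pool of baseline rates; defaults to
#'   an internal pool drawn from [default_lambda_pool()]'s distribution.
#' @param L_range,nu_range,phi_shape Generating ranges as described above.
#' @param indicator_per_pair When `TRUE` the between-group indicator is
#'   drawn per tuple and pair instead of once per tuple (default `FALSE`).
#' @param seed Integer seed.
#' @return A list of class `pbb_sim`: `counts` (a [paired_counts()] table),
#'   `scaling` (the true factors), `truth` (tibble: `tuple_id`, `label`,
#'   `lambda`, `phi`, `f`, `g`, `indicator`), `condition` (per-pair labels)
#'   and `draws` (matrices `nu`, `M`, `mu`, `mu_prime`).
#' @examples
#' sim <- simulate_dataset(n_tuples = 50, n_within_de = 5, n_pairs = 4, seed = 1)
#' table(sim$truth$label)
#' @export
simulate_dataset <- function(n_pairs = 4, n_groups = 1, n_tuples = 10000,
                             n_within_de = 1000, n_between_de = 0,
                             b = 2, d = 2, noise_family = c("beta", "minimax"),
                             lambda_pool = NULL,
                             L_range = c(30000, 90000), nu_range = c(-2, 2),
                             phi_shape = c(1, 10),
                             indicator_per_pair = FALSE, seed = 1L) {
  noise_family <- match.arg(noise_family)
  if (!n_groups %in% c(1L, 2L)) abort("`n_groups` must be 1 or 2.")
  if (n_between_de > 0 && n_groups != 2L) {
    abort("between-group differential expression requires `n_groups = 2`.")
  }
  if (n_within_de + n_between_de > n_tuples) {
    abort("`n_within_de + n_between_de` cannot exceed `n_tuples`.")
  }
  if (b < 0 || d < 0) abort("`b` and `d` must be non-negative.")
  if (!is.null(lambda_pool) && any(lambda_pool <= 0)) {
    abort("`lambda_pool` must be strictly positive.")
  }

  np <- as.integer(n_pairs) * as.integer(n_groups)
  C <- as.integer(n_tuples)
  label <- rep("NULL", C)
  if (n_within_de > 0) label[seq_len(n_within_de)] <- "WITHIN_DE"
  if (n_between_de > 0) label[n_within_de + seq_len(n_between_de)] <- "BETWEEN_DE"
  de <- label != "NULL"
  between <- label == "BETWEEN_DE"
  condition <- rep(paste0("G", seq_len(n_groups)), each = n_pairs)
  in_first <- condition == condition[1]

  with_seed(seed, function() {
    pool <- lambda_pool %||% lambda_from_uniform(runif(10000L))
    lambda <- pool[sample.int(length(pool), C, replace = TRUE)]
    L <- runif(np, L_range[1], L_range[2])
    L_prime <- runif(np, L_range[1], L_range[2])
    phi <- pmin(pmax(rbeta(C, phi_shape[1], phi_shape[2]), 1e-8), PHI_MAX)
    f <- ifelse(de, runif(C, -b, b), 0)
    g <- ifelse(between, runif(C, -d, d), 0)
    I_mat <- matrix(0L, C, np)
    if (any(between)) {
      if (indicator_per_pair) {
        I_mat[between, ] <- matrix(
          sample(0:1, sum(between) * np, replace = TRUE), sum(between), np
        )
      } else {
        I_mat[between, ] <- sample(0:1, sum(between), replace = TRUE)
      }
    }
    nu <- matrix(runif(C * np, nu_range[1], nu_range[2]), C, np)
    Q <- 2^nu

    # per-pair log2 effect from the between-condition scaling
    G_mat <- matrix(0, C, np)
    if (any(between)) {
      first_cols <- matrix(rep(in_first, each = C), C, np)
      G_mat <- ifelse(first_cols, I_mat * g, (1 - I_mat) * g)
      G_mat[!between, ] <- 0
    }
    mu <- 2^(matrix(f, C, np) + G_mat)
    mu_prime <- 2^(-(matrix(f, C, np) + G_mat))

    msum <- mu + mu_prime
    a_shape <- mu / msum * (1 - phi) / phi
    b_shape <- mu_prime / msum * (1 - phi) / phi

    u_M <- matrix(runif(C * np), C, np)
    if (noise_family == "beta") {
      M <- matrix(stats::qbeta(u_M, a_shape, b_shape), C, np)
    } else {
      mean_t <- mu / msum
      var_t <- mean_t * (1 - mean_t) * phi
      M <- matrix(NA_real_, C, np)
      # one solver call per distinct (mean, variance) target within a tuple
      for (ci in seq_len(C)) {
        targets <- unique(round(cbind(mean_t[ci, ], var_t[ci, ]), 14))
        for (t_row in seq_len(nrow(targets))) {
          sel <- abs(mean_t[ci, ] - targets[t_row, 1]) < 1e-13
          m_t <- targets[t_row, 1]
          v_t <- targets[t_row, 2]
          if (v_t < 1e-4 * m_t * (1 - m_t)) {
            # below the solver's resolution both families degenerate to the mean
            M[ci, sel] <- m_t
          } else {
            par <- solve_minimax_parameters(m_t, v_t)
            M[ci, sel] <- qminimax(u_M[ci, sel], par$alpha, par$beta)
          }
        }
      }
    }
    M <- pmin(pmax(M, 1e-12), 1 - 1e-12)

    mean_u <- lambda * L_mat(L, C) * Q * M
    mean_v <- lambda * L_mat(L_prime, C) * Q * (1 - M)
    u <- matrix(rpois(C * np, mean_u), C, np)
    v <- matrix(rpois(C * np, mean_v), C, np)

    pairs <- paste0(condition, "_", sequence(rep(n_pairs, n_groups)))
    counts <- paired_counts(u, v,
      tuple_ids = paste0("t", seq_len(C)), pairs = pairs
    )
    structure(
      list(
        counts = counts,
        scaling = scaling_factors(L, L_prime, pairs),
        truth = tibble::tibble(
          tuple_id = counts$tuple_id, label = label, lambda = lambda,
          phi = phi, f = f, g = g,
          indicator = if (indicator_per_pair) NA_integer_ else I_mat[, 1]
        ),
        condition = condition,
        draws = list(nu = nu, M = M, mu = mu, mu_prime = mu_prime, I = I_mat),
        config = list(
          n_pairs = n_pairs, n_groups = n_groups, n_tuples = n_tuples,
          n_within_de = n_within_de, n_between_de = n_between_de,
          b = b, d = d, noise_family = noise_family, L_range = L_range,
          nu_range = nu_range, phi_shape = phi_shape,
          indicator_per_pair = indicator_per_pair, seed = seed
        )
      ),
      class = "pbb_sim"
    )
  })
}

# replicate a per-pair vector across C tuple rows
L_mat <- function(x, C) matrix(rep(x, each = C), C, length(x))

#' @export
print.pbb_sim <- function(x, ...) {
  cfg <- x$config
  cat("Simulated paired dataset:", cfg$n_tuples, "tuples x",
    cfg$n_pairs * cfg$n_groups, "sample pairs\n"
  )
  cat("  labels:", paste(names(table(x$truth$label)),
    table(x$truth$label),
    sep = "=", collapse = ", "
  ), "\n")
  cat("  noise family:", cfg$noise_family, " seed:", cfg$seed, "\n")
  invisible(x)
}
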