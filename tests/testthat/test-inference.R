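theta_fixture <- function(model, pis, phis) {
  structure(
    lapply(seq_along(model$sets), function(q) {
      tibble::tibble(Pi = pis[[q]], phi = phis[[q]])
    }),
    class = "pbb_theta"
  )
}

test_that("marginal likelihood with one Theta entry is the plain product", {
  pc <- make_counts(c(12, 7, 20), c(9, 11, 18))
  model <- model_spec("m", list(1:2, 3))
  th <- theta_fixture(model, list(0.6, 0.5), list(0.1, 0.05))
  got <- marginal_log_likelihood(pc, model, th)
  want <- sum(log_betabinom_pair(c(12, 7), c(9, 11), 0.6, 0.1)) +
    log_betabinom_pair(20, 18, 0.5, 0.05)
  expect_equal(got, unname(want), tolerance = 1e-12)
})

test_that("marginal likelihood is invariant to duplicating Theta entries", {
  pc <- make_counts(c(12, 7, 20), c(9, 11, 18))
  model <- model_spec("m", list(1:3))
  th1 <- theta_fixture(model, list(c(0.4, 0.6)), list(c(0.02, 0.2)))
  th2 <- theta_fixture(
    model, list(rep(c(0.4, 0.6), 3)), list(rep(c(0.02, 0.2), 3))
  )
  expect_equal(
    marginal_log_likelihood(pc, model, th1),
    marginal_log_likelihood(pc, model, th2),
    tolerance = 1e-12
  )
})

test_that("marginal likelihood matches a plain-arithmetic brute force", {
  withr::local_seed(5)
  u <- c(4, 9, 2)
  v <- c(6, 3, 5)
  pc <- make_counts(u, v)
  model <- model_spec("m", list(1:2, 3))
  pis <- list(c(0.3, 0.5, 0.62, 0.8), c(0.45, 0.5, 0.55, 0.7))
  phis <- list(c(0.01, 0.1, 0.2, 0.05), c(0.3, 0.02, 0.15, 0.08))
  th <- theta_fixture(model, pis, phis)

  # brute force in probability space, double loop, no log-sum-exp
  pmf <- function(uu, vv, Pi, phi) exp(log_betabinom_pair(uu, vv, Pi, phi))
  total <- 1
  for (q in 1:2) {
    idx <- model$sets[[q]]
    acc <- 0
    for (k in 1:4) {
      prod_k <- 1
      for (i in idx) prod_k <- prod_k * pmf(u[i], v[i], pis[[q]][k], phis[[q]][k])
      acc <- acc + prod_k
    }
    total <- total * acc / 4
  }
  expect_equal(marginal_log_likelihood(pc, model, th), log(total), tolerance = 1e-10)
})

test_that("marginal likelihood converges to the exact atom-weighted mean", {
  withr::local_seed(8)
  u <- c(14, 6, 11, 9)
  v <- c(7, 12, 10, 8)
  pc <- make_counts(u, v)
  model <- model_spec("m", list(1:4))
  atoms <- cbind(Pi = c(0.35, 0.5, 0.7), phi = c(0.02, 0.1, 0.25))
  w <- c(0.2, 0.5, 0.3)
  lik_at <- function(Pi, phi) exp(sum(log_betabinom_pair(u, v, Pi, phi)))
  exact <- sum(w * mapply(lik_at, atoms[, 1], atoms[, 2]))

  K <- 1e4
  pick <- sample(1:3, K, replace = TRUE, prob = w)
  th <- theta_fixture(model, list(atoms[pick, 1]), list(atoms[pick, 2]))
  got <- exp(marginal_log_likelihood(pc, model, th))
  vals <- mapply(lik_at, atoms[pick, 1], atoms[pick, 2])
  se <- sd(vals) / sqrt(K)
  expect_lt(abs(got - exact), 3 * se)
})

test_that("BIC priors follow the assignment proportions with a floor", {
  m_null <- model_spec("null", list(1:4), fixed = 0.5)
  m_free <- model_spec("free", list(1:4))

  expect_equal(
    estimate_priors_bic(matrix(c(-5, -3), ncol = 1), list(m_null), n_pairs = 4),
    c(null = 1)
  )

  # unanimous winner: the loser keeps the floor after renormalisation
  ll <- cbind(rep(-10, 5), rep(-2, 5))
  pr <- estimate_priors_bic(ll, list(m_null, m_free), n_pairs = 4)
  expect_equal(unname(pr), c(1e-3, 1) / (1 + 1e-3), tolerance = 1e-12)

  # hand-computed BIC comparison: k = (0, 1), n_pairs = 4
  # tuple 1: -2*(-3) vs -2*(-2.5) + log 4 -> 6 vs 6.386 -> null
  # tuple 2: -2*(-4) vs -2*(-3) + log 4  -> 8 vs 7.386 -> free
  # tuple 3: -2*(-1) vs -2*(-0.35) + log4-> 2 vs 2.086 -> null
  ll <- rbind(c(-3, -2.5), c(-4, -3), c(-1, -0.35))
  pr <- estimate_priors_bic(ll, list(m_null, m_free), n_pairs = 4)
  expect_equal(unname(pr), c(2 / 3, 1 / 3), tolerance = 1e-12)

  # exact BIC ties break toward the more parsimonious model
  pr_tie <- estimate_priors_bic(matrix(c(-2, -2 + log(4) / 2), 1),
    list(m_null, m_free),
    n_pairs = 4
  )
  expect_gt(pr_tie["null"], pr_tie["free"])
})

test_that("posterior probabilities follow Bayes' rule", {
  expect_equal(
    posterior_probabilities(log(c(0.1, 0.1, 0.1)), rep(1 / 3, 3)),
    rep(1 / 3, 3)
  )
  expect_equal(
    posterior_probabilities(log(c(0.2, 0.1)), c(0.5, 0.5)),
    c(2 / 3, 1 / 3)
  )
  withr::local_seed(14)
  for (i in 1:20) {
    ll <- log(runif(5))
    pr <- runif(5)
    pr <- pr / sum(pr)
    plain <- exp(ll) * pr / sum(exp(ll) * pr)
    expect_equal(posterior_probabilities(ll, pr), plain, tolerance = 1e-12)
  }
  # rows of a matrix normalise to one
  ll <- matrix(log(runif(12)), 4)
  post <- posterior_probabilities(ll, c(0.2, 0.3, 0.5))
  expect_equal(unname(rowSums(post)), rep(1, 4), tolerance = 1e-10)
  expect_error(posterior_probabilities(log(c(0.1, 0.2)), c(0.9, 0.5)), "sum to 1")
})

test_that("the FDR estimator averages one minus the posterior down the ranking", {
  f <- estimate_fdr(c(1, 1, 1))
  expect_equal(f$fdr, rep(0, 3))

  f <- estimate_fdr(c(0.99, 0.95, 0.90))
  expect_equal(f$fdr[f$rank == 2], 0.03)
  expect_equal(f$fdr[f$rank == 3], (0.01 + 0.05 + 0.10) / 3)

  withr::local_seed(3)
  p <- runif(50)
  f <- estimate_fdr(p)
  expect_true(all(diff(f$fdr[order(f$rank)]) >= -1e-12))
  # output stays aligned to input order
  expect_equal(f$posterior, p)
})

test_that("FDR selection takes the largest admissible prefix", {
  expect_identical(
    select_at_fdr(estimate_fdr(c(0.99, 0.95, 0.90), c("a", "b", "c")), 0.05),
    c("a", "b")
  )
  expect_identical(select_at_fdr(c(0.5, 0.5, 0.5), 0.05), character(0))
  expect_identical(
    select_at_fdr(estimate_fdr(c(1, 0.8), c("a", "b")), 0),
    "a"
  )
})

test_that("the full posterior fit is coherent and honours all-zero tuples", {
  withr::local_seed(99)
  sim <- simulate_dataset(
    n_pairs = 4, n_tuples = 150, n_within_de = 25, b = 3, seed = 17
  )
  # force one all-zero tuple
  df <- tibble::as_tibble(as.data.frame(sim$counts))
  df[3, -1] <- 0L
  pc <- as_paired_counts(df)
  fit <- pbb_posterior(pc,
    reps = rep("R", 4), scaling = sim$scaling,
    theta_size = 30, seed = 17
  )
  expect_equal(unname(rowSums(fit$posterior)), rep(1, 150), tolerance = 1e-10)
  expect_equal(sum(fit$priors), 1, tolerance = 1e-12)
  expect_equal(unname(fit$posterior[3, ]), c(0.5, 0.5))

  td <- tidy(fit)
  expect_equal(nrow(td), 300)
  g <- glance(fit)
  expect_equal(g$n_all_zero, 1L)
  expect_s3_class(autoplot(fit), "ggplot")

  # fixed priors override BIC estimation
  fit2 <- pbb_posterior(pc,
    reps = rep("R", 4), scaling = sim$scaling,
    theta_size = 30, seed = 17, priors = c(0.9, 0.1)
  )
  expect_equal(unname(fit2$priors), c(0.9, 0.1))
})
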