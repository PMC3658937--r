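test_that("simulation is reproducible and labels match the configuration", {
  s1 <- simulate_dataset(n_tuples = 300, n_within_de = 40, n_pairs = 3, seed = 5)
  s2 <- simulate_dataset(n_tuples = 300, n_within_de = 40, n_pairs = 3, seed = 5)
  expect_identical(counts_first(s1$counts), counts_first(s2$counts))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_dataset(n_tuples = 300, n_within_de = 40, n_pairs = 3, seed = 6)
  expect_false(identical(counts_first(s1$counts), counts_first(s3$counts)))

  expect_equal(sum(s1$truth$label == "WITHIN_DE"), 40)
  expect_equal(sum(s1$truth$label == "NULL"), 260)

  s4 <- simulate_dataset(
    n_tuples = 200, n_within_de = 30, n_between_de = 20,
    n_pairs = 2, n_groups = 2, seed = 1
  )
  expect_equal(unname(table(s4$truth$label)[c("BETWEEN_DE", "NULL", "WITHIN_DE")]),
    c(20, 150, 30),
    ignore_attr = TRUE
  )
  expect_error(
    simulate_dataset(n_tuples = 10, n_between_de = 5, n_groups = 1),
    "n_groups"
  )
  expect_error(simulate_dataset(n_tuples = 10, n_within_de = 20), "exceed")
})

test_that("a configuration without differential expression is all-null", {
  s <- simulate_dataset(n_tuples = 100, n_within_de = 0, n_pairs = 4, seed = 2)
  expect_true(all(s$truth$label == "NULL"))
  expect_true(all(s$draws$mu == 1))
  expect_true(all(s$draws$mu_prime == 1))
  expect_true(all(s$truth$f == 0))
})

test_that("the noise proportion has the configured beta mean", {
  # null tuples: E[M] = mu/(mu + mu') = 1/2 regardless of phi
  s <- simulate_dataset(n_tuples = 5000, n_within_de = 0, n_pairs = 4, seed = 9)
  m <- as.vector(s$draws$M)
  se <- sd(m) / sqrt(length(m))
  expect_lt(abs(mean(m) - 0.5), 3 * se)

  # within-DE tuples: E[M] = 2^f / (2^f + 2^-f)
  s2 <- simulate_dataset(n_tuples = 2000, n_within_de = 2000, b = 2, n_pairs = 4, seed = 10)
  want <- 2^s2$truth$f / (2^s2$truth$f + 2^-s2$truth$f)
  got <- rowMeans(s2$draws$M)
  expect_lt(abs(mean(got - want)), 0.01)
})

test_that("count means follow the Poisson mixture construction", {
  # fixed baseline and depth, no individual effects: E[u] = lambda * L * E[M]
  s <- simulate_dataset(
    n_tuples = 10000, n_within_de = 0, n_pairs = 1,
    lambda_pool = 1e-3, L_range = c(60000, 60000), nu_range = c(0, 0),
    seed = 4
  )
  u <- counts_first(s$counts)[, 1]
  expect_lt(abs(mean(u) - 30), 3 * sd(u) / sqrt(length(u)))
})

test_that("conditional on the pair total, null counts are beta-binomial", {
  # pin the dispersion near 0.1 with a concentrated generating beta
  s <- simulate_dataset(
    n_tuples = 8000, n_within_de = 0, n_pairs = 1,
    lambda_pool = 2e-3, L_range = c(50000, 50000), nu_range = c(0, 0),
    phi_shape = c(1e5 * 0.1, 1e5 * 0.9), seed = 12
  )
  u <- counts_first(s$counts)[, 1]
  v <- counts_second(s$counts)[, 1]
  keep <- (u + v) == 100
  expect_gt(sum(keep), 150)
  # bin the conditional distribution and chi-square against the model pmf
  p_model <- exp(log_betabinom_pair(0:100, 100:0, 0.5, 0.1))
  breaks <- c(-1, seq(19, 79, by = 10), 101)
  obs <- table(cut(u[keep], breaks))
  expp <- vapply(seq_len(length(breaks) - 1), function(j) {
    sum(p_model[(0:100) > breaks[j] & (0:100) <= breaks[j + 1]])
  }, numeric(1))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = expp))
  expect_gt(gof$p.value, 0.01)
})

test_that("the baseline-rate pool is positive, seeded and prefix-stable", {
  p1 <- default_lambda_pool(500, seed = 3)
  p2 <- default_lambda_pool(500, seed = 3)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0))
  p3 <- default_lambda_pool(2000, seed = 3)
  expect_identical(p3[1:500], p1)
  expect_false(identical(default_lambda_pool(500, seed = 4), p1))
  # rates stay in the range that yields realistic depths at L ~ 6e4
  expect_true(all(p1 >= 1e-6 & p1 <= 1e-1))
})

test_that("minimax parameters solve the printed moment equations", {
  s <- solve_minimax_parameters(0.5, 1 / 12)
  expect_equal(s$alpha, 1, tolerance = 1e-6)
  expect_equal(s$beta, 1, tolerance = 1e-6)

  s <- solve_minimax_parameters(1 / 3, 1 / 18)
  expect_equal(s$alpha, 1, tolerance = 1e-6)
  expect_equal(s$beta, 2, tolerance = 1e-6)

  withr::local_seed(20)
  for (i in 1:25) {
    m <- runif(1, 0.05, 0.95)
    v <- runif(1, 0.001, 0.9) * m * (1 - m)
    s <- solve_minimax_parameters(m, v)
    expect_lt(abs(minimax_moment(1, s$alpha, s$beta) - m), 1e-8)
    expect_lt(abs(minimax_moment(2, s$alpha, s$beta) - minimax_moment(1, s$alpha, s$beta)^2 - v), 1e-8)
  }
  expect_error(solve_minimax_parameters(0.5, 0.3), "infeasible")
})

test_that("minimax sampling matches its analytic distribution", {
  withr::local_seed(21)
  x <- rminimax(20000, 2.5, 4)
  expect_true(all(x > 0 & x < 1))
  ks <- suppressWarnings(ks.test(x, function(q) pminimax(q, 2.5, 4)))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(x) - minimax_moment(1, 2.5, 4)), 3 * sd(x) / sqrt(length(x)))
})

test_that("beta and minimax noise with matched moments are comparable", {
  sb <- simulate_dataset(n_tuples = 600, n_within_de = 100, b = 2, n_pairs = 4, seed = 30)
  sm <- simulate_dataset(
    n_tuples = 600, n_within_de = 100, b = 2, n_pairs = 4,
    noise_family = "minimax", seed = 30
  )
  # identical non-noise draws (same stream), matched noise moments
  expect_identical(sb$truth$lambda, sm$truth$lambda)
  expect_identical(sb$truth$f, sm$truth$f)
  mb <- rowMeans(sb$draws$M)
  mm <- rowMeans(sm$draws$M)
  expect_lt(mean(abs(mb - mm)), 0.05)
  expect_lt(abs(var(as.vector(sb$draws$M)) - var(as.vector(sm$draws$M))), 0.01)
})

test_that("the between-group indicator can be drawn per tuple or per pair", {
  s <- simulate_dataset(
    n_tuples = 100, n_within_de = 0, n_between_de = 100,
    n_pairs = 4, n_groups = 2, d = 2, seed = 40
  )
  # per tuple (default): constant across the pair columns
  expect_true(all(apply(s$draws$I, 1, function(r) length(unique(r)) == 1)))
  s2 <- simulate_dataset(
    n_tuples = 100, n_within_de = 0, n_between_de = 100,
    n_pairs = 4, n_groups = 2, d = 2, indicator_per_pair = TRUE, seed = 40
  )
  expect_gt(sum(apply(s2$draws$I, 1, function(r) length(unique(r)) > 1)), 50)
})
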