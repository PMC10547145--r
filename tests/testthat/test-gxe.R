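test_that("variance and correlation functions evaluate their closed forms", {
  expect_equal(genetic_variance_at(0, 0, 5, 10), 1)
  expect_equal(genetic_variance_at(log(2), 0, 5, 10), 2)
  expect_equal(genetic_variance_at(0, 0.5, 12, 10), exp(1))

  expect_equal(genetic_correlation_between(0.3, 4, 4), 1)
  expect_equal(genetic_correlation_between(0, 1, 99), 1)
  expect_equal(genetic_correlation_between(0.1, 0, 10), exp(-1))
  expect_equal(genetic_correlation_between(0.1, 10, 0), exp(-1)) # symmetry
  expect_error(genetic_correlation_between(-0.1, 1, 2), ">= 0")

  expect_equal(residual_variance_at(0, 0, 3, 3), 1)
  expect_equal(residual_variance_at(0, -0.2, 8, 3), exp(-1))
  v <- residual_variance_at(0, -0.2, 1:10, 5)
  expect_true(all(diff(v) < 0))
})

test_that("two-environment GxE variance follows the Robertson decomposition", {
  expect_equal(two_environment_gxe_variance(1.7, 1.7, 1), 0)
  expect_equal(two_environment_gxe_variance(1, 1, 0.5), 1)
  expect_equal(two_environment_gxe_variance(1, 4, 1), 1)   # (1 - 2)^2
  # equal-variance branch: 2 sg2 (1 - rho)
  expect_equal(two_environment_gxe_variance(0.8, 0.8, 0.3),
               2 * 0.8 * (1 - 0.3))
  expect_error(two_environment_gxe_variance(-1, 1, 0), ">= 0")
  expect_error(two_environment_gxe_variance(1, 1, 1.2), "rho")
})

test_that("assemble_covariance reduces to the polygenic covariance and obeys K's zeros", {
  K <- compute_kinship(ped_sibs())
  q <- c(8, 12, 10, 14)
  Sig0 <- assemble_covariance(K, gxe_parameters(0, 0, 0, 0, 0), q)
  expect_identical(Sig0, K + diag(4))   # exp(0) = 1 exactly
  p0 <- gxe_parameters(alpha_g = log(0.7), alpha_e = log(0.5))
  Sig <- assemble_covariance(K, p0, q)
  expect_equal(Sig, K * 0.7 + diag(4) * 0.5, tolerance = 1e-15)
  # unrelated pair stays zero whatever the environment
  p1 <- gxe_parameters(0.2, 0.3, 0.1, 0.1, -0.2)
  Sig1 <- assemble_covariance(K, p1, q)
  expect_identical(Sig1["p1", "p2"], 0)
  # direct off-diagonal value: K = 0.5, gamma_g = 0, lambda |dq| = 1
  K2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  Sig2 <- assemble_covariance(K2, gxe_parameters(0, 0, 0.1, 0, 0), c(0, 10))
  expect_equal(Sig2[1, 2], 0.5 * exp(-1))
})

test_that("the covariance is invariant to a constant shift of the environment", {
  K <- compute_kinship(ped_inbred20())
  set.seed(60)
  q <- rnorm(20, 10, 4)
  p <- gxe_parameters(0.1, 0.25, 0.07, -0.1, -0.15)
  expect_equal(assemble_covariance(K, p, q),
               assemble_covariance(K, p, q + 100), tolerance = 1e-9)
})

test_that("the GxE covariance is positive definite across random parameters", {
  set.seed(61)
  for (s in 1:10) {
    ped <- random_small_pedigree(200 + s)
    K <- compute_kinship(ped)
    q <- rnorm(nrow(K), 10, 4)
    p <- gxe_parameters(runif(1, -1, 1), runif(1, -0.4, 0.4),
                        runif(1, 0, 0.3), runif(1, -1, 1),
                        runif(1, -0.3, 0.3))
    Sig <- assemble_covariance(K, p, q)
    expect_silent(chol(Sig))
  }
})

test_that("diagonal variance is increasing in q under positive gamma_g", {
  K <- diag(10)
  q <- sort(rnorm(10, 10, 4))
  Sig <- assemble_covariance(K, gxe_parameters(0, 0.4, 0.05, 0, 0), q)
  expect_true(all(diff(diag(Sig)) > 0))
})

test_that("GxE log-likelihood reduces to the polygenic one and matches the dense oracle", {
  set.seed(62)
  ped <- random_small_pedigree(301)
  K <- compute_kinship(ped)
  n <- nrow(K)
  y <- rnorm(n)
  q <- rnorm(n, 10, 4)
  X <- matrix(1, n, 1)
  p0 <- gxe_parameters(alpha_g = log(0.8), alpha_e = log(0.4), beta = 0.2)
  expect_equal(gxe_loglik(p0, y, X, K, q),
               polygenic_loglik(0.8, 0.4, 0.2, y, X, K), tolerance = 1e-10)

  for (s in 1:8) {
    ped <- random_small_pedigree(400 + s)
    K <- compute_kinship(ped)
    n <- nrow(K)
    y <- rnorm(n)
    q <- rnorm(n, 10, 4)
    X <- matrix(1, n, 1)
    p <- gxe_parameters(runif(1, -1, 1), runif(1, -0.3, 0.3),
                        runif(1, 0, 0.2), runif(1, -1, 1),
                        runif(1, -0.2, 0.2), beta = rnorm(1))
    ll <- gxe_loglik(p, y, X, K, q)
    oracle <- dense_mvn_loglik(y, rep(p$beta, n),
                               assemble_covariance(K, p, q))
    expect_equal(ll, oracle, tolerance = 1e-8)
  }
})

test_that("GxE log-likelihood is invariant under joint permutation", {
  set.seed(63)
  ped <- generate_pedigree(n_families = 2, seed = 8)
  K <- compute_kinship(ped)
  n <- nrow(K)
  y <- rnorm(n)
  q <- rnorm(n, 10, 4)
  p <- gxe_parameters(0.1, 0.2, 0.05, -0.2, -0.1, beta = 0)
  perm <- sample(n)
  expect_equal(gxe_loglik(p, y, matrix(1, n, 1), K, q),
               gxe_loglik(p, y[perm], matrix(1, n, 1), K[perm, perm],
                          q[perm]),
               tolerance = 1e-10)
})

test_that("the fully constrained GxE fit reproduces the polygenic fit", {
  sim <- sim_small(n_families = 10, seed = 70,
                   params = gxe_parameters(alpha_g = log(0.5),
                                           alpha_e = log(0.5)))
  poly <- fit_polygenic(sim$y, sim$X, sim$K, blocks = sim$blocks,
                        se = FALSE)
  red <- fit_gxe(sim$y, sim$X, sim$K, sim$q,
                 constraints = c("gamma_g", "lambda_g", "gamma_e"),
                 blocks = sim$blocks, polygenic = poly, se = FALSE)
  expect_lt(abs(red$loglik - poly$loglik), 1e-6)
  expect_equal(exp(red$params$alpha_g), poly$sigma_g2, tolerance = 1e-3)
  expect_identical(red$params$gamma_g, 0)
  expect_identical(red$params$lambda_g, 0)
  expect_identical(red$params$gamma_e, 0)
})

test_that("nested GxE fits respect the likelihood ordering", {
  sim <- sim_small(n_families = 10, seed = 71)
  poly <- fit_polygenic(sim$y, sim$X, sim$K, blocks = sim$blocks,
                        se = FALSE)
  full <- fit_gxe(sim$y, sim$X, sim$K, sim$q, blocks = sim$blocks,
                  polygenic = poly, se = FALSE)
  for (con in list("gamma_g", "lambda_g", "gamma_e",
                   c("gamma_g", "gamma_e"))) {
    red <- fit_gxe(sim$y, sim$X, sim$K, sim$q, constraints = con,
                   blocks = sim$blocks, polygenic = poly, se = FALSE)
    expect_lte(red$loglik, full$loglik + 1e-6)
    for (p in con) expect_identical(red$params[[p]], 0)
  }
})

test_that("the full fit recovers generating parameters within sampling error", {
  truth <- gxe_parameters(0, 0.3, 0.05, 0, -0.2)
  sim <- sim_small(n_families = 42, seed = 72, params = truth)
  fit <- fit_gxe(sim$y, sim$X, sim$K, sim$q, blocks = sim$blocks)
  expect_true(fit$converged)
  for (p in c("alpha_g", "gamma_g", "lambda_g", "alpha_e", "gamma_e")) {
    se <- fit$ses[[p]]
    if (is.na(se)) se <- 0.1   # lambda at boundary: allow a fixed margin
    expect_lt(abs(fit$params[[p]] - truth[[p]]), max(4 * se, 0.02))
  }
  # constrained parameters must stay free here
  expect_length(fit$constraints, 0)
})

test_that("invalid parameters and misaligned inputs are rejected", {
  expect_error(gxe_parameters(lambda_g = -0.5), "lambda_g")
  expect_error(gxe_parameters(alpha_g = Inf), "finite")
  K <- diag(3)
  expect_error(assemble_covariance(K, gxe_parameters(), c(1, 2)), "align")
  expect_error(environment_index(c(1, NA)), "finite")
})
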