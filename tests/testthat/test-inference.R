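test_that("mixture chi-square distributions validate their components", {
  expect_error(mixture_chisq(c(0, 0, 1)), "point-mass")
  expect_error(mixture_chisq(c(1, 2), weights = c(0.7, 0.7)), "sum to 1")
  expect_error(mixture_chisq(-1), ">= 0")
  m <- mixture_chisq(c(2, 3))
  expect_equal(m$weights, c(0.5, 0.5))
})

test_that("mixture upper tails reproduce the published reference values", {
  mix23 <- mixture_chisq(c(2, 3))
  mix01 <- mixture_chisq(c(0, 1))
  chi1 <- mixture_chisq(1)
  expect_equal(mixture_sf(0, mix23), 1)
  expect_equal(mixture_sf(0, mix01), 1)
  # genetic-correlation test, boundary mixture
  expect_equal(round(mixture_sf(3.2609, mix01), 4), 0.0355)
  # residual-variance test, chi-square 1 df
  expect_equal(round(mixture_sf(6.8624, chi1), 4), 0.0088)
  # overall GxE-vs-polygenic test
  expect_equal(round(mixture_sf(10.303, mix23), 2), 0.01)
})

test_that("mixture survival function is monotone and matches single components", {
  mix <- mixture_chisq(c(0, 1))
  x <- seq(0, 20, by = 0.25)
  sf <- mixture_sf(x, mix)
  expect_true(all(diff(sf) <= 0))
  expect_equal(mixture_sf(x, mixture_chisq(3)),
               pchisq(x, 3, lower.tail = FALSE))
  # the point mass contributes only at exactly zero
  expect_equal(mixture_sf(1e-12, mix),
               0.5 * pchisq(1e-12, 1, lower.tail = FALSE))
})

test_that("lrt computes the statistic, clamps noise, and warns on real inversions", {
  r <- lrt(-547.8467, -542.6951, mixture_chisq(c(2, 3)))
  expect_equal(r$statistic, 10.3032, tolerance = 1e-9)
  expect_equal(round(r$statistic, 3), 10.303)
  r2 <- lrt(-538.4800, -534.6063, mixture_chisq(1))
  expect_equal(r2$statistic, 7.7474, tolerance = 1e-9)
  same <- lrt(-100, -100, mixture_chisq(c(2, 3)))
  expect_identical(same$statistic, 0)
  expect_equal(same$p_value, 1)
  tiny <- lrt(-100 + 1e-8, -100, mixture_chisq(1))
  expect_identical(tiny$statistic, 0)
  expect_warning(lrt(-99, -100, mixture_chisq(1)), "negative")
})

test_that("stage-1 test wires the 2/3-df mixture and checks its inputs", {
  sim <- sim_small(n_families = 8, seed = 80)
  poly <- fit_polygenic(sim$y, sim$X, sim$K, blocks = sim$blocks,
                        se = FALSE)
  full <- fit_gxe(sim$y, sim$X, sim$K, sim$q, blocks = sim$blocks,
                  polygenic = poly, se = FALSE)
  s1 <- stage1_test(poly, full)
  expect_equal(s1$reference$df, c(2L, 3L))
  expect_equal(s1$statistic, -2 * (poly$loglik - full$loglik),
               tolerance = 1e-9)
  poly_bad <- poly
  poly_bad$n <- poly$n - 1L
  expect_error(stage1_test(poly_bad, full), "mismatched")
  red <- fit_gxe(sim$y, sim$X, sim$K, sim$q, constraints = "gamma_g",
                 blocks = sim$blocks, polygenic = poly, se = FALSE)
  expect_error(stage1_test(poly, red), "unconstrained")
})

test_that("stage-2 tests enforce constraint bookkeeping and use the right references", {
  sim <- sim_small(n_families = 8, seed = 81)
  poly <- fit_polygenic(sim$y, sim$X, sim$K, blocks = sim$blocks,
                        se = FALSE)
  full <- fit_gxe(sim$y, sim$X, sim$K, sim$q, blocks = sim$blocks,
                  polygenic = poly, se = FALSE)
  nulls <- lapply(stats::setNames(c("gamma_g", "lambda_g", "gamma_e"),
                                  c("gamma_g", "lambda_g", "gamma_e")),
                  function(p) fit_gxe(sim$y, sim$X, sim$K, sim$q,
                                      constraints = p, blocks = sim$blocks,
                                      polygenic = poly, se = FALSE))
  tests <- stage2_tests(full, nulls)
  expect_named(tests, c("gamma_g", "lambda_g", "gamma_e"))
  expect_equal(tests$gamma_g$reference$df, 1L)
  expect_equal(tests$lambda_g$reference$df, c(0L, 1L))
  expect_equal(tests$gamma_e$reference$df, 1L)
  for (t2 in tests) expect_gte(t2$statistic, 0)
  # mismatched constraints are refused
  expect_error(stage2_tests(full, list(gamma_g = nulls$lambda_g)),
               "bookkeeping")
})

fake_gxe_fit <- function(mles, ses, boundary_lambda = FALSE) {
  structure(list(params = do.call(gxe_parameters, as.list(mles)),
                 ses = ses, loglik = 0, constraints = character(0),
                 converged = TRUE, n = 100,
                 boundary = c(alpha_g = FALSE, gamma_g = FALSE,
                              lambda_g = boundary_lambda, alpha_e = FALSE,
                              gamma_e = FALSE),
                 vcov = NULL),
            class = "gxe_fit")
}

fake_lrt <- function(p) {
  structure(list(statistic = 1, p_value = p,
                 reference = mixture_chisq(1), null_loglik = 0,
                 alt_loglik = 0.5), class = "lrt_result")
}

test_that("select_model drops a parameter only when screened AND non-significant", {
  ses <- c(alpha_g = 0.1, gamma_g = 0.05, lambda_g = 0.02, alpha_e = 0.1,
           gamma_e = 0.03)
  # SE > |MLE| and formal p = 0.96 -> dropped
  f1 <- fake_gxe_fit(c(alpha_g = 0, gamma_g = 0.01, lambda_g = 0.1,
                       alpha_e = 0, gamma_e = -0.2), ses)
  sel <- select_model(f1, list(gamma_g = fake_lrt(0.96),
                               lambda_g = fake_lrt(0.01),
                               gamma_e = fake_lrt(0.01)))
  expect_identical(sel, "gamma_g")
  # all |MLE| > 2 SE -> nothing dropped
  f2 <- fake_gxe_fit(c(alpha_g = 0, gamma_g = 0.3, lambda_g = 0.1,
                       alpha_e = 0, gamma_e = -0.2), ses)
  expect_length(select_model(f2, list(gamma_g = fake_lrt(0.001),
                                      lambda_g = fake_lrt(0.001),
                                      gamma_e = fake_lrt(0.001))), 0)
  # screened but formally significant -> retained
  sel3 <- select_model(f1, list(gamma_g = fake_lrt(0.01),
                                lambda_g = fake_lrt(0.5),
                                gamma_e = fake_lrt(0.5)))
  expect_false("gamma_g" %in% sel3)
  # a lambda_g boundary estimate (SE undefined) screens as unimportant
  f3 <- fake_gxe_fit(c(alpha_g = 0, gamma_g = 0.3, lambda_g = 0,
                       alpha_e = 0, gamma_e = -0.2),
                     replace(ses, "lambda_g", NA_real_),
                     boundary_lambda = TRUE)
  sel4 <- select_model(f3, list(gamma_g = fake_lrt(0.001),
                                lambda_g = fake_lrt(0.9),
                                gamma_e = fake_lrt(0.001)))
  expect_identical(sel4, "lambda_g")
})

test_that("run_two_stage produces a complete, internally consistent report", {
  sim <- sim_small(n_families = 14, seed = 82,
                   params = gxe_parameters(0, 0.3, 0.05, 0, -0.2))
  rep <- run_two_stage(sim$y, sim$X, sim$K, sim$q, blocks = sim$blocks)
  expect_s3_class(rep, "two_stage_report")
  expect_s3_class(rep$stage1, "lrt_result")
  expect_lte(length(rep$stage2), 3)
  expect_gte(length(rep$stage2), 3 - length(rep$dropped))
  expect_true(rep$model_used %in% c("full", "reduced"))
  # dropped parameters are constrained in the selected alternative
  expect_setequal(rep$alternative$constraints, rep$dropped)
  # stage-2 alternatives reference the selected model's log-likelihood
  for (t2 in rep$stage2)
    expect_equal(t2$alt_loglik, rep$alternative$loglik)
  # nesting: polygenic <= alternative <= full
  expect_lte(rep$polygenic$loglik, rep$alternative$loglik + 1e-6)
  expect_lte(rep$alternative$loglik, rep$full$loglik + 1e-6)
  expect_output(print(rep), "Two-stage GxE testing report")
})

test_that("likelihood-ratio statistics are additive over nested fits", {
  sim <- sim_small(n_families = 10, seed = 83)
  poly <- fit_polygenic(sim$y, sim$X, sim$K, blocks = sim$blocks,
                        se = FALSE)
  full <- fit_gxe(sim$y, sim$X, sim$K, sim$q, blocks = sim$blocks,
                  polygenic = poly, se = FALSE)
  mid <- fit_gxe(sim$y, sim$X, sim$K, sim$q,
                 constraints = c("gamma_g", "lambda_g"),
                 blocks = sim$blocks, polygenic = poly, se = FALSE)
  base <- fit_gxe(sim$y, sim$X, sim$K, sim$q,
                  constraints = c("gamma_g", "lambda_g", "gamma_e"),
                  blocks = sim$blocks, polygenic = poly, se = FALSE)
  l_ac <- -2 * (base$loglik - full$loglik)
  l_ab <- -2 * (base$loglik - mid$loglik)
  l_bc <- -2 * (mid$loglik - full$loglik)
  expect_equal(l_ac, l_ab + l_bc, tolerance = 1e-6)
})

test_that("p-values format to four significant figures with scientific tails", {
  expect_identical(format_pvalue(0.0355), "0.0355")
  expect_identical(format_pvalue(0.01097), "0.01097")
  expect_identical(format_pvalue(7.9e-05), "7.9E-05")
  expect_identical(format_pvalue(1), "1")
})
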