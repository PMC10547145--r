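#' GxE model parameters
#'
#' Parameter vector of the continuous-environment GxE covariance model.
#' The additive genetic variance and the genetic correlation are
#' exponential functions of the environment index q:
#' variance `exp(alpha_g + gamma_g (q_i - q_bar))`, correlation
#' `exp(-lambda_g |q_i - q_j|)`; the residual environmental variance is
#' `exp(alpha_e + gamma_e (q_i - q_bar))`. `gamma_g = 0` and
#' `lambda_g = 0` recover genetic variance homogeneity and genetic
#' correlation stationarity at unity, i.e. the polygenic model with
#' `sigma_g^2 = exp(alpha_g)`, `sigma_e^2 = exp(alpha_e)`.
#'
#' @param alpha_g log additive genetic variance at `q = q_bar`.
#' @param gamma_g genetic-variance slope per environment unit.
#' @param lambda_g genetic-correlation decay rate per environment unit
#'   (must be >= 0).
#' @param alpha_e log residual environmental variance at `q = q_bar`.
#' @param gamma_e residual-variance slope per environment unit.
#' @param beta optional fixed-effect coefficient vector.
#' @return object of class `gxe_parameters`.
#' @export
gxe_parameters <- function(alpha_g = 0, gamma_g = 0, lambda_g = 0,
                           alpha_e = 0, gamma_e = 0, beta = NULL) {
  vals <- c(alpha_g, gamma_g, lambda_g, alpha_e, gamma_e)
  if (any(!is.finite(vals))) stop("GxE parameters must be finite")
  if (lambda_g < 0) stop("lambda_g must be >= 0")
  structure(list(alpha_g = alpha_g, gamma_g = gamma_g, lambda_g = lambda_g,
                 alpha_e = alpha_e, gamma_e = gamma_e, beta = beta),
            class = "gxe_parameters")
}

#' Environment index
#'
#' Wraps an environment vector together with its sample mean `q_bar`
#' (the centering point of the variance functions). `q_bar` is recomputed
#' from `q` as supplied, i.e. over the analysis sample after any
#' missing-data exclusion.
#'
#' @param q numeric vector of per-individual environment values (finite).
#' @return object of class `environment_index`: list with `q` and `q_bar`.
#' @export
environment_index <- function(q) {
  if (inherits(q, "environment_index")) return(q)
  if (inherits(q, "corrected_environment")) q <- q$q_corrected
  q <- as.numeric(q)
  if (any(!is.finite(q))) stop("environment values must be finite")
  structure(list(q = q, q_bar = mean(q)), class = "environment_index")
}

#' Environment-dependent additive genetic variance
#'
#' `sigma_g^2(q) = exp(alpha_g + gamma_g (q - q_bar))`.
#'
#' @inheritParams gxe_parameters
#' @param q environment value(s).
#' @param q_bar sample mean of the environment index.
#' @return positive variance(s).
#' @export
genetic_variance_at <- function(alpha_g, gamma_g, q, q_bar) {
  exp(alpha_g + gamma_g * (q - q_bar))
}

#' Genetic correlation between two environment values
#'
#' `rho_g(q_i, q_j) = exp(-lambda_g |q_i - q_j|)`, the correlation between
#' the genetic effects expressed by the same polygenotype at two
#' environment values; an exponential decay in the environmental
#' difference, symmetric in (i, j), equal to 1 when `lambda_g = 0`
#' (stationarity at unity) or when the environments coincide.
#'
#' @inheritParams gxe_parameters
#' @param q_i,q_j environment values.
#' @return correlation(s) in (0, 1].
#' @export
genetic_correlation_between <- function(lambda_g, q_i, q_j) {
  if (lambda_g < 0) stop("lambda_g must be >= 0")
  exp(-lambda_g * abs(q_i - q_j))
}

#' Environment-dependent residual environmental variance
#'
#' `delta(q) = exp(alpha_e + gamma_e (q - q_bar))`.
#'
#' @inheritParams gxe_parameters
#' @param q environment value(s).
#' @param q_bar sample mean of the environment index.
#' @return positive variance(s).
#' @export
residual_variance_at <- function(alpha_e, gamma_e, q, q_bar) {
  exp(alpha_e + gamma_e * (q - q_bar))
}

#' GxE variance between two environments
#'
#' Interaction variance between two discrete environments:
#' `sigma_gDelta^2 = sigma_g1^2 + sigma_g2^2 - 2 rho_g sigma_g1 sigma_g2`
#' (Robertson form), which equals `2 sigma_g^2 (1 - rho_g)` when the
#' variances are equal and is zero iff the variances are equal and
#' `rho_g = 1` — the two conditions whose joint failure constitutes GxE.
#'
#' @param sigma_g1_sq,sigma_g2_sq additive genetic variances in the two
#'   environments (>= 0).
#' @param rho_g genetic correlation between environments, in `[-1, 1]`.
#' @return non-negative GxE variance.
#' @export
two_environment_gxe_variance <- function(sigma_g1_sq, sigma_g2_sq, rho_g) {
  if (any(sigma_g1_sq < 0) || any(sigma_g2_sq < 0))
    stop("variances must be >= 0")
  if (any(abs(rho_g) > 1)) stop("rho_g must be in [-1, 1]")
  sigma_g1_sq + sigma_g2_sq - 2 * rho_g * sqrt(sigma_g1_sq * sigma_g2_sq)
}

# Psi block for environment values q (matrix of genetic variances and
# covariances): psi_ij = exp(alpha_g + gamma_g (q_i + q_j - 2 q_bar)/2
#                            - lambda_g |q_i - q_j|).
psi_matrix <- function(params, q, q_bar) {
  dq <- q - q_bar
  S <- outer(dq, dq, "+") / 2
  D <- abs(outer(q, q, "-"))
  exp(params$alpha_g + params$gamma_g * S - params$lambda_g * D)
}

#' Assemble the GxE phenotypic covariance matrix
#'
#' `Sigma = K (Hadamard) Psi + Delta`, where
#' `Psi_ij = exp(alpha_g + gamma_g (q_i + q_j - 2 q_bar)/2 - lambda_g |q_i - q_j|)`
#' collects the genetic variance/covariance functions and
#' `Delta = diag(exp(alpha_e + gamma_e (q_i - q_bar)))` the residual
#' environmental variance function. With `gamma_g = lambda_g = gamma_e = 0`
#' this reduces exactly to the polygenic covariance
#' `K exp(alpha_g) + I exp(alpha_e)`. Sigma is positive definite for every
#' valid parameter set (K is PSD, the exponential-decay correlation is a
#' valid 1-d kernel, and Delta is diagonal-positive).
#'
#' @param K additive relationship matrix.
#' @param params [gxe_parameters()].
#' @param env [environment_index()] (or numeric vector) aligned with `K`.
#' @return symmetric positive definite matrix.
#' @export
assemble_covariance <- function(K, params, env) {
  env <- environment_index(env)
  if (length(env$q) != nrow(K))
    stop("environment index does not align with kinship matrix")
  Sig <- K * psi_matrix(params, env$q, env$q_bar)
  diag(Sig) <- diag(Sig) +
    residual_variance_at(params$alpha_e, params$gamma_e, env$q, env$q_bar)
  if (any(!is.finite(Sig))) stop("non-finite covariance entries")
  Sig
}

#' GxE model log-likelihood
#'
#' Exact multivariate-normal log-density of `y` under the GxE covariance
#' from [assemble_covariance()]. If `params$beta` is `NULL` the fixed
#' effects are profiled by generalized least squares.
#'
#' @param params [gxe_parameters()].
#' @inheritParams polygenic_loglik
#' @param env [environment_index()] or numeric vector aligned with `y`.
#' @return log-likelihood (scalar).
#' @export
gxe_loglik <- function(params, y, X = NULL, K, env, blocks = NULL) {
  env <- environment_index(env)
  n <- length(y)
  X <- default_design(X, n)
  check_alignment(y, X, K)
  if (length(env$q) != n) stop("environment index does not align with y")
  blocks <- resolve_blocks(K, blocks)
  Sig <- lapply(blocks, function(b) {
    S <- K[b, b, drop = FALSE] * psi_matrix(params, env$q[b], env$q_bar)
    diag(S) <- diag(S) + residual_variance_at(params$alpha_e, params$gamma_e,
                                              env$q[b], env$q_bar)
    S
  })
  out <- mvn_profile(y, X, Sig, blocks, beta = params$beta)
  if (!out$ok) stop("covariance not positive definite")
  out$loglik
}

gxe_par_names <- c("alpha_g", "gamma_g", "lambda_g", "alpha_e", "gamma_e")

#' Fit the continuous-environment GxE model by maximum likelihood
#'
#' Maximizes the GxE log-likelihood over the free parameters among
#' `(alpha_g, gamma_g, lambda_g, alpha_e, gamma_e)`, with `beta` profiled
#' by GLS. Parameters named in `constraints` are held at exactly 0.
#' Optimization is projected L-BFGS-B with an analytic score vector,
#' `lambda_g` bounded in `[0, 50/range(q)]` (a correlation below e^-50 is
#' numerically zero), warm-started from the polygenic fit
#' (`alpha_g = log sigma_g^2_hat`, `alpha_e = log sigma_e^2_hat`, slopes
#' 0). When `lambda_g` is free the `lambda_g = 0`-constrained candidate is
#' always fitted as well; if the interior search does not beat it the
#' boundary solution is returned exactly, so boundary likelihood-ratio
#' statistics are exactly zero.
#'
#' Standard errors come from the numerically estimated observed
#' information of the free parameters; at a `lambda_g = 0` boundary the
#' SE of `lambda_g` is `NA` (information is one-sided there).
#'
#' @inheritParams gxe_loglik
#' @param constraints character subset of
#'   `c("gamma_g", "lambda_g", "gamma_e")` to fix at 0.
#' @param polygenic optional pre-computed [fit_polygenic()] result on the
#'   same data, used as the warm start.
#' @param se compute standard errors? (default `TRUE`).
#' @param min_n minimum sample size (default 30).
#' @return object of class `gxe_fit`: list with `params`
#'   ([gxe_parameters()] at the MLEs, including `beta`), `beta_hat`,
#'   `ses` (named; `NA` for constrained or boundary parameters), `loglik`,
#'   `constraints`, `converged`, `n`, `boundary` (named logical),
#'   `vcov` (free parameters) and, when computed, `lambda0_fit` (the
#'   `lambda_g = 0`-constrained candidate fit).
#' @export
fit_gxe <- function(y, X = NULL, K, env, constraints = character(),
                    blocks = NULL, polygenic = NULL, se = TRUE,
                    min_n = 30) {
  n <- length(y)
  if (n < min_n) stop("insufficient sample: n = ", n, " (< ", min_n, ")")
  env <- environment_index(env)
  if (length(env$q) != n) stop("environment index does not align with y")
  X <- default_design(X, n)
  check_alignment(y, X, K)
  blocks <- resolve_blocks(K, blocks)
  bad <- setdiff(constraints, c("gamma_g", "lambda_g", "gamma_e"))
  if (length(bad)) stop("unknown constraint(s): ", paste(bad, collapse = ", "))
  constraints <- unique(constraints)

  if (is.null(polygenic))
    polygenic <- fit_polygenic(y, X, K, blocks = blocks, se = FALSE,
                               min_n = min_n)
  s2 <- polygenic$sigma_g2 + polygenic$sigma_e2
  warm <- c(alpha_g = log(max(polygenic$sigma_g2, 1e-3 * s2)),
            gamma_g = 0, lambda_g = 0,
            alpha_e = log(max(polygenic$sigma_e2, 1e-3 * s2)),
            gamma_e = 0)

  qrange <- diff(range(env$q))
  lambda_max <- if (qrange > 0) 50 / qrange else 0

  # per-block precomputations
  pre <- lapply(blocks, function(b) {
    qb <- env$q[b]
    dq <- qb - env$q_bar
    list(K = K[b, b, drop = FALSE],
         dq = dq,
         S = outer(dq, dq, "+") / 2,
         D = abs(outer(qb, qb, "-")))
  })

  sig_of <- function(p) {
    lapply(pre, function(z) {
      S <- z$K * exp(p[["alpha_g"]] + p[["gamma_g"]] * z$S -
                       p[["lambda_g"]] * z$D)
      diag(S) <- diag(S) + exp(p[["alpha_e"]] + p[["gamma_e"]] * z$dq)
      S
    })
  }
  objfns <- function(free) {
    full_par <- function(th) {
      p <- c(alpha_g = 0, gamma_g = 0, lambda_g = 0, alpha_e = 0,
             gamma_e = 0)
      p[free] <- th
      p
    }
    negll <- function(th) {
      out <- mvn_profile(y, X, sig_of(full_par(th)), blocks)
      if (!out$ok) return(1e12)
      -out$loglik
    }
    neggr <- function(th) {
      p <- full_par(th)
      Sig <- sig_of(p)
      out <- mvn_profile(y, X, Sig, blocks, keep = TRUE)
      if (!out$ok) return(numeric(length(free)))
      derivs <- lapply(seq_along(blocks), function(k) {
        z <- pre[[k]]
        G <- z$K * exp(p[["alpha_g"]] + p[["gamma_g"]] * z$S -
                         p[["lambda_g"]] * z$D)
        d <- exp(p[["alpha_e"]] + p[["gamma_e"]] * z$dq)
        all_d <- list(alpha_g = G, gamma_g = G * z$S, lambda_g = -G * z$D,
                      alpha_e = d, gamma_e = d * z$dq)
        all_d[free]
      })
      -mvn_score(y, X, Sig, blocks, derivs, out$beta, out$U)
    }
    list(full_par = full_par, negll = negll, neggr = neggr)
  }
  fit_free <- function(free, start) {
    fns <- objfns(free)
    lower <- rep(-Inf, length(free)); upper <- rep(Inf, length(free))
    lower[free == "lambda_g"] <- 0
    upper[free == "lambda_g"] <- lambda_max
    lower[free %in% c("alpha_g", "alpha_e")] <- log(s2) - 30
    upper[free %in% c("alpha_g", "alpha_e")] <- log(s2) + 10
    opt <- stats::optim(start[free], fns$negll, fns$neggr,
                        method = "L-BFGS-B", lower = lower, upper = upper,
                        control = list(factr = 1e6, maxit = 300))
    par <- fns$full_par(opt$par)
    # guard against floating-point dust below the box constraint
    if (par[["lambda_g"]] < 0) par[["lambda_g"]] <- 0
    fin <- mvn_profile(y, X, sig_of(par), blocks)
    list(par = par, free = free, loglik = fin$loglik,
         beta = fin$beta, converged = opt$convergence == 0, opt = opt)
  }

  free <- setdiff(gxe_par_names, constraints)
  lambda_free <- "lambda_g" %in% free && lambda_max > 0

  lam0 <- NULL
  if (lambda_free) {
    lam0 <- fit_free(setdiff(free, "lambda_g"), warm)
    # interior searches: from the boundary solution, and from moderate and
    # small decay rates
    mean_gap <- mean(vapply(pre, function(z)
      if (length(z$dq) > 1) mean(z$D[upper.tri(z$D)]) else 0, numeric(1)))
    lam_try <- if (mean_gap > 0) min(0.2 / mean_gap, lambda_max / 2)
               else lambda_max / 2
    st2 <- lam0$par; st2["lambda_g"] <- lam_try
    st3 <- lam0$par; st3["lambda_g"] <- lam_try / 5
    cand <- list(fit_free(free, lam0$par),
                 fit_free(free, st2),
                 fit_free(free, st3))
    fit <- cand[[which.max(vapply(cand, `[[`, numeric(1), "loglik"))]]
    if (fit$par[["lambda_g"]] == 0 || fit$loglik <= lam0$loglik + 1e-9) {
      # the boundary solution is the MLE: keep whichever search found the
      # better optimum of the remaining parameters, exactly, on both sides
      if (fit$loglik <= lam0$loglik) {
        fit <- lam0
        fit$par[["lambda_g"]] <- 0
        fit$free <- free
      } else {
        lam0 <- fit
      }
    } else if (lam0$loglik > fit$loglik) {
      lam0 <- fit  # cannot happen for nested fits; guard anyway
    }
  } else {
    if ("lambda_g" %in% free) free <- setdiff(free, "lambda_g") # degenerate q
    fit <- fit_free(free, warm)
  }

  at_boundary <- c(alpha_g = FALSE, gamma_g = FALSE,
                   lambda_g = lambda_free && fit$par[["lambda_g"]] == 0,
                   alpha_e = FALSE, gamma_e = FALSE)

  ses <- stats::setNames(rep(NA_real_, 5), gxe_par_names)
  vcov <- NULL
  if (se) {
    # observed information over all free parameters; at a lambda_g = 0
    # boundary this uses the two-sided curvature (the likelihood extends
    # smoothly to slightly negative decay rates while Sigma stays PD);
    # if that leaves the PD region, fall back to the interior parameters
    # and leave SE(lambda_g) undefined
    hess_sets <- list(free, setdiff(free, names(at_boundary)[at_boundary]))
    for (hess_free in unique(hess_sets)) {
      hf <- objfns(hess_free)
      H <- tryCatch(stats::optimHess(fit$par[hess_free], hf$negll,
                                     hf$neggr),
                    error = function(e) NULL)
      if (!is.null(H)) {
        Vi <- tryCatch(solve(H), error = function(e) NULL)
        if (!is.null(Vi) && all(diag(Vi) > 0) && all(is.finite(Vi))) {
          vcov <- Vi
          dimnames(vcov) <- list(hess_free, hess_free)
          ses[hess_free] <- sqrt(diag(Vi))
          break
        }
      }
    }
  }

  params <- gxe_parameters(fit$par[["alpha_g"]], fit$par[["gamma_g"]],
                           fit$par[["lambda_g"]], fit$par[["alpha_e"]],
                           fit$par[["gamma_e"]], beta = fit$beta)
  out <- structure(list(params = params,
                        beta_hat = stats::setNames(fit$beta, colnames(X)),
                        ses = ses, loglik = fit$loglik,
                        constraints = constraints,
                        converged = fit$converged, n = n,
                        boundary = at_boundary, vcov = vcov,
                        q_bar = env$q_bar),
                   class = "gxe_fit")
  if (!is.null(lam0))
    out$lambda0_fit <- list(loglik = lam0$loglik, par = lam0$par,
                            beta = lam0$beta, converged = lam0$converged)
  out
}

#' @export
print.gxe_fit <- function(x, ...) {
  cat("GxE variance-components fit (ML)\n")
  cat(sprintf("  n = %d, lnL = %.4f%s\n", x$n, x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (length(x$constraints))
    cat("  constrained to 0:", paste(x$constraints, collapse = ", "), "\n")
  for (p in gxe_par_names) {
    flag <- if (p %in% x$constraints) "  (constrained)"
            else if (isTRUE(x$boundary[[p]])) "  (boundary)"
            else ""
    cat(sprintf("  %-9s = %9.4f  SE = %s%s\n", p, x$params[[p]],
                ifelse(is.na(x$ses[[p]]), "NA",
                       sprintf("%.4f", x$ses[[p]])), flag))
  }
  invisible(x)
}
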