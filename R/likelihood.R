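# Internal multivariate-normal likelihood machinery.
#
# All model covariances in this package are block-diagonal across families
# (K (Hadamard) Psi keeps K's zero pattern), so log-likelihoods, GLS fixed
# effects and score vectors are accumulated block by block via Cholesky
# factors. Gradients use the envelope theorem: with beta profiled at its
# GLS value the profile score in the covariance parameters equals the
# partial derivative at fixed beta.

# Evaluate ln L = -1/2 [ n ln 2pi + ln|Sigma| + r' Sigma^-1 r ] where
# Sigma is given as a list of per-block matrices. If beta is NULL it is
# profiled by GLS. Returns -Inf (with ok = FALSE) if any block is not
# positive definite.
mvn_profile <- function(y, X, Sig, blocks, beta = NULL, keep = FALSE) {
  n <- length(y)
  p <- ncol(X)
  logdet <- 0
  XtSiX <- matrix(0, p, p)
  XtSiy <- numeric(p)
  ytSiy <- 0
  Us <- if (keep) vector("list", length(blocks)) else NULL
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    U <- tryCatch(chol(Sig[[k]]), error = function(e) NULL)
    if (is.null(U)) return(list(ok = FALSE, loglik = -Inf))
    logdet <- logdet + 2 * sum(log(diag(U)))
    yt <- backsolve(U, y[b], transpose = TRUE)
    Xt <- backsolve(U, X[b, , drop = FALSE], transpose = TRUE)
    XtSiX <- XtSiX + crossprod(Xt)
    XtSiy <- XtSiy + crossprod(Xt, yt)[, 1]
    ytSiy <- ytSiy + sum(yt^2)
    if (keep) Us[[k]] <- U
  }
  if (is.null(beta)) {
    beta <- tryCatch(solve(XtSiX, XtSiy), error = function(e) NULL)
    if (is.null(beta)) return(list(ok = FALSE, loglik = -Inf))
    quad <- ytSiy - sum(beta * XtSiy)
  } else {
    quad <- ytSiy - 2 * sum(beta * XtSiy) + sum(beta * (XtSiX %*% beta))
  }
  list(ok = TRUE,
       loglik = -0.5 * (n * log(2 * pi) + logdet + quad),
       beta = as.numeric(beta), U = Us, XtSiX = XtSiX)
}

# Score vector d lnL / d theta_k = -1/2 [ tr(Sigma^-1 D_k) - u' D_k u ],
# u = Sigma^-1 r, r = y - X beta_hat, accumulated over blocks. `derivs` is
# a list (over blocks) of lists (over parameters) of derivative matrices;
# diagonal derivative matrices may be passed as plain vectors.
mvn_score <- function(y, X, Sig, blocks, derivs, beta, U = NULL) {
  npar <- length(derivs[[1]])
  g <- numeric(npar)
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    Uk <- if (is.null(U)) chol(Sig[[k]]) else U[[k]]
    Si <- chol2inv(Uk)
    r <- y[b] - X[b, , drop = FALSE] %*% beta
    u <- as.numeric(Si %*% r)
    for (j in seq_len(npar)) {
      D <- derivs[[k]][[j]]
      if (is.matrix(D)) {
        tr <- sum(Si * D)
        qf <- sum(u * (D %*% u))
      } else {            # diagonal derivative stored as a vector
        tr <- sum(diag(Si) * D)
        qf <- sum(u^2 * D)
      }
      g[j] <- g[j] + (qf - tr)
    }
  }
  g / 2
}

# Dense (single-block) index set for a matrix without family structure.
single_block <- function(n) list(seq_len(n))

# Resolve a blocks argument: NULL -> connected components of K.
resolve_blocks <- function(K, blocks = NULL) {
  if (is.null(blocks)) relatedness_blocks(K) else blocks
}

check_alignment <- function(y, X, K) {
  n <- length(y)
  if (nrow(K) != n || ncol(K) != n)
    stop("kinship matrix dimension (", nrow(K), ") does not match phenotype length (", n, ")")
  if (nrow(X) != n)
    stop("fixed-effect design has ", nrow(X), " rows; expected ", n)
  invisible(n)
}

default_design <- function(X, n) {
  if (is.null(X)) return(matrix(1, n, 1, dimnames = list(NULL, "intercept")))
  X <- as.matrix(X)
  if (!nrow(X)) stop("empty design matrix")
  X
}
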