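#' BLUP additive genetic values
#'
#' Best linear unbiased prediction of the additive genetic effects under a
#' fitted polygenic model:
#' `g_hat = sigma_g^2 K Sigma^-1 (q - X beta_hat)` with
#' `Sigma = K sigma_g^2 + I sigma_e^2` at the fit's MLEs. For `K = I` this
#' reduces to an elementwise shrink by h^2 of the fixed-effect residual;
#' in a pedigree it pools information across relatives.
#'
#' @param fit a [fit_polygenic()] result for `q` as the phenotype.
#' @param q the phenotype the fit was obtained on (e.g. a heritable
#'   environment index such as education years).
#' @param X fixed-effect design used in the fit; `NULL` = intercept-only.
#' @param K additive relationship matrix aligned with `q`.
#' @param blocks optional family blocks of `K`.
#' @return numeric vector of predicted genetic values, aligned with `q`.
#' @export
blup_genetic_values <- function(fit, q, X = NULL, K, blocks = NULL) {
  stopifnot(inherits(fit, "polygenic_fit"))
  n <- length(q)
  X <- default_design(X, n)
  check_alignment(q, X, K)
  if (length(fit$beta_hat) != ncol(X))
    stop("design matrix does not match the fit's coefficient vector")
  if (fit$sigma_g2 == 0) return(numeric(n))
  blocks <- resolve_blocks(K, blocks)
  r <- q - as.numeric(X %*% fit$beta_hat)
  g <- numeric(n)
  for (b in blocks) {
    Kb <- K[b, b, drop = FALSE]
    Sb <- Kb * fit$sigma_g2
    diag(Sb) <- diag(Sb) + fit$sigma_e2
    g[b] <- fit$sigma_g2 * as.numeric(Kb %*% solve(Sb, r[b]))
  }
  g
}

#' Genetically corrected environment
#'
#' Subtracts BLUP-predicted additive genetic values from a heritable
#' environment variable, leaving a version that reflects primarily
#' environmental effects. The corrected variable is the focal environment
#' index passed to the GxE model; it is not re-standardized, so slope
#' parameters keep the original units (e.g. per education year).
#'
#' @inheritParams blup_genetic_values
#' @param q raw environment values.
#' @return object of class `corrected_environment`: list with `q_raw`,
#'   `g_hat`, `q_corrected` (`= q_raw - g_hat`) and `fit`.
#' @export
correct_environment <- function(q, fit, X = NULL, K, blocks = NULL) {
  g <- blup_genetic_values(fit, q, X, K, blocks)
  structure(list(q_raw = q, g_hat = g, q_corrected = q - g, fit = fit),
            class = "corrected_environment")
}

#' @export
print.corrected_environment <- function(x, ...) {
  cat("BLUP-corrected environment\n")
  cat(sprintf("  n = %d, source-fit h2 = %s\n", length(x$q_raw),
              format_h2(x$fit$h2, x$fit$se_h2)))
  cat(sprintf("  var(q_raw) = %.3f, var(g_hat) = %.3f, var(q_corrected) = %.3f\n",
              stats::var(x$q_raw), stats::var(x$g_hat),
              stats::var(x$q_corrected)))
  invisible(x)
}
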