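#' Mixture of chi-square distributions
#'
#' Reference null distributions for likelihood-ratio tests with boundary
#' parameters: finite mixtures of chi-square components, where a component
#' with `df = 0` is a point mass at zero. The stage-1 comparison of the
#' full GxE model against the polygenic model uses a 50:50 mixture of
#' chi-squares with 2 and 3 df (three extra parameters, one of them —
#' `lambda_g` — on its boundary under the null); the `lambda_g` test uses
#' a 50:50 mixture of a point mass at 0 and a chi-square with 1 df; the
#' `gamma_g` and `gamma_e` tests use a plain chi-square with 1 df.
#'
#' @param df integer vector of degrees of freedom (0 = point mass at 0).
#' @param weights mixture weights, summing to 1; default equal.
#' @return object of class `mixture_chisq`.
#' @export
mixture_chisq <- function(df, weights = NULL) {
  df <- as.integer(df)
  if (any(df < 0)) stop("degrees of freedom must be >= 0")
  if (sum(df == 0L) > 1L) stop("at most one point-mass component")
  if (is.null(weights)) weights <- rep(1 / length(df), length(df))
  if (length(weights) != length(df)) stop("weights do not match components")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12)
    stop("weights must be non-negative and sum to 1")
  structure(list(df = df, weights = weights), class = "mixture_chisq")
}

# the three reference distributions of the testing protocol
stage1_reference   <- function() mixture_chisq(c(2L, 3L))
lambda_reference   <- function() mixture_chisq(c(0L, 1L))
chisq1_reference   <- function() mixture_chisq(1L)

#' Upper-tail probability of a chi-square mixture
#'
#' `P(X >= x) = sum_k w_k P(chisq_df_k >= x)`, with a `df = 0` component
#' contributing its full weight at `x = 0` and nothing for `x > 0`.
#'
#' @param x non-negative quantile(s).
#' @param ref a [mixture_chisq()].
#' @return upper-tail probability in `[0, 1]`, vectorized over `x`.
#' @export
mixture_sf <- function(x, ref) {
  if (!inherits(ref, "mixture_chisq")) stop("ref must be a mixture_chisq")
  if (any(x < 0)) stop("x must be >= 0")
  out <- numeric(length(x))
  for (k in seq_along(ref$df)) {
    out <- out + ref$weights[k] *
      if (ref$df[k] == 0L) as.numeric(x <= 0)
      else stats::pchisq(x, ref$df[k], lower.tail = FALSE)
  }
  out
}

#' Likelihood-ratio test with a mixture chi-square reference
#'
#' `Lambda = -2 (lnL_null - lnL_alt)`; values in `(-1e-6, 0)` — numerical
#' noise from independently optimized nested fits — are clamped to 0, and
#' anything below -1e-6 triggers a warning that the nested fits should be
#' re-optimized.
#'
#' @param null_loglik,alt_loglik maximized log-likelihoods of the nested
#'   (constrained) and alternative model.
#' @param ref a [mixture_chisq()] reference distribution.
#' @return object of class `lrt_result`: list with `statistic`,
#'   `p_value`, `reference`, `null_loglik`, `alt_loglik`.
#' @export
lrt <- function(null_loglik, alt_loglik, ref) {
  stat <- -2 * (null_loglik - alt_loglik)
  if (stat < -1e-6)
    warning("negative LRT statistic (", format(stat),
            "): null fit beats alternative; refit recommended")
  stat <- max(stat, 0)
  structure(list(statistic = stat, p_value = mixture_sf(stat, ref),
                 reference = ref, null_loglik = null_loglik,
                 alt_loglik = alt_loglik),
            class = "lrt_result")
}

#' Stage-1 test: full GxE model against the polygenic model
#'
#' The GxE model adds three parameters (`gamma_g`, `lambda_g`, `gamma_e`)
#' to the polygenic model, with `lambda_g` on its boundary under the null;
#' the LRT statistic is referred to a 50:50 mixture of chi-squares with 2
#' and 3 df.
#'
#' @param polygenic a [fit_polygenic()] result.
#' @param full_gxe the unconstrained [fit_gxe()] result on the same data.
#' @return an [lrt()] result.
#' @export
stage1_test <- function(polygenic, full_gxe) {
  stopifnot(inherits(polygenic, "polygenic_fit"), inherits(full_gxe, "gxe_fit"))
  if (polygenic$n != full_gxe$n)
    stop("mismatched samples: polygenic n = ", polygenic$n,
         ", GxE n = ", full_gxe$n)
  if (length(full_gxe$constraints))
    stop("stage-1 alternative must be the unconstrained GxE fit")
  lrt(polygenic$loglik, full_gxe$loglik, stage1_reference())
}

stage2_reference <- function(param) {
  switch(param,
         gamma_g = chisq1_reference(),
         lambda_g = lambda_reference(),
         gamma_e = chisq1_reference(),
         stop("no stage-2 test for parameter: ", param))
}

#' Stage-2 single-parameter tests
#'
#' Tests each of `gamma_g` (genetic variance homogeneity, chi-square 1
#' df), `lambda_g` (genetic correlation of 1; 50:50 point-mass/chi-square
#' 1 df) and `gamma_e` (residual variance homogeneity, chi-square 1 df)
#' by comparing a null fit that constrains exactly that parameter (beyond
#' the alternative's constraints) against the alternative fit.
#'
#' @param alternative a [fit_gxe()] result (full or reduced model).
#' @param null_fits named list of [fit_gxe()] results; names identify the
#'   tested parameter and each fit's constraints must equal the
#'   alternative's constraints plus that parameter.
#' @return named list of [lrt()] results.
#' @export
stage2_tests <- function(alternative, null_fits) {
  stopifnot(inherits(alternative, "gxe_fit"))
  out <- list()
  for (param in names(null_fits)) {
    nf <- null_fits[[param]]
    stopifnot(inherits(nf, "gxe_fit"))
    want <- sort(union(alternative$constraints, param))
    if (!identical(sort(nf$constraints), want))
      stop("constraint bookkeeping mismatch for ", param, ": null fit has {",
           paste(nf$constraints, collapse = ", "), "}, expected {",
           paste(want, collapse = ", "), "}")
    if (param %in% alternative$constraints)
      stop("parameter ", param, " is already constrained in the alternative")
    out[[param]] <- lrt(nf$loglik, alternative$loglik,
                        stage2_reference(param))
  }
  out
}

#' Reduced-model selection by the SE-versus-MLE screen
#'
#' A GxE parameter is judged statistically unimportant — and constrained
#' to 0 in a reduced model — when both (a) its SE exceeds the magnitude of
#' its MLE and (b) its formal single-parameter LRT is non-significant at
#' `alpha`. Parameters whose `|MLE| > 2 SE` (or that fail only one
#' condition) are retained.
#'
#' @param full a [fit_gxe()] result with SEs.
#' @param formal_tests named list of [lrt()] results from
#'   [stage2_tests()] against the full model.
#' @param alpha significance level of the formal test (default 0.05).
#' @return character vector of parameters to constrain (possibly empty).
#' @export
select_model <- function(full, formal_tests, alpha = 0.05) {
  stopifnot(inherits(full, "gxe_fit"))
  drop <- character(0)
  for (param in intersect(c("gamma_g", "lambda_g", "gamma_e"),
                          names(formal_tests))) {
    mle <- full$params[[param]]
    se <- full$ses[[param]]
    # a boundary estimate (lambda_g = 0, SE undefined) screens as
    # unimportant: any SE exceeds |MLE| = 0
    screened <- if (is.na(se)) isTRUE(full$boundary[[param]]) else se > abs(mle)
    if (screened && formal_tests[[param]]$p_value >= alpha)
      drop <- c(drop, param)
  }
  drop
}

#' Run the two-stage GxE testing protocol
#'
#' Fits the polygenic and full GxE models, performs the stage-1 LRT
#' (mixture chi-square 2/3 df), screens the three GxE parameters by the
#' SE-versus-MLE rule combined with their formal single-parameter tests,
#' refits a reduced model when any parameter is judged unimportant, and
#' runs the stage-2 tests of the remaining parameters against the selected
#' (full or reduced) alternative. Stage-2 null fits re-optimize all
#' remaining free parameters.
#'
#' @inheritParams fit_gxe
#' @param alpha significance level used by the reduced-model screen.
#' @return object of class `two_stage_report`: list with `polygenic`,
#'   `full` and `alternative` fits, `stage1` and `stage2` [lrt()] results,
#'   `formal_tests` (against the full model), `dropped` (constraint set of
#'   the reduced model) and `model_used` (`"full"` or `"reduced"`).
#' @export
run_two_stage <- function(y, X = NULL, K, env, blocks = NULL, alpha = 0.05,
                          min_n = 30) {
  env <- environment_index(env)
  blocks <- resolve_blocks(K, blocks)
  polygenic <- fit_polygenic(y, X, K, blocks = blocks, min_n = min_n)
  full <- fit_gxe(y, X, K, env, blocks = blocks, polygenic = polygenic,
                  min_n = min_n)
  stage1 <- stage1_test(polygenic, full)

  null_fit <- function(alt, param) {
    fit_gxe(y, X, K, env, constraints = union(alt$constraints, param),
            blocks = blocks, polygenic = polygenic, se = FALSE,
            min_n = min_n)
  }
  params3 <- c("gamma_g", "lambda_g", "gamma_e")
  formal_nulls <- lapply(stats::setNames(params3, params3),
                         function(p) null_fit(full, p))
  formal <- stage2_tests(full, formal_nulls)

  dropped <- select_model(full, formal, alpha = alpha)
  if (length(dropped)) {
    alternative <- fit_gxe(y, X, K, env, constraints = dropped,
                           blocks = blocks, polygenic = polygenic,
                           min_n = min_n)
    remaining <- setdiff(params3, dropped)
    nulls <- lapply(stats::setNames(remaining, remaining),
                    function(p) null_fit(alternative, p))
    stage2 <- stage2_tests(alternative, nulls)
  } else {
    alternative <- full
    stage2 <- formal
  }

  structure(list(polygenic = polygenic, full = full,
                 alternative = alternative, stage1 = stage1,
                 formal_tests = formal, dropped = dropped,
                 stage2 = stage2,
                 model_used = if (length(dropped)) "reduced" else "full"),
            class = "two_stage_report")
}

#' Format a p-value for reporting
#'
#' Four significant figures; scientific notation below 1e-3 (table
#' convention).
#'
#' @param p probability.
#' @return character.
#' @export
format_pvalue <- function(p) {
  ifelse(p < 1e-3, sprintf("%.1E", p), sprintf("%.4g", p))
}

#' @export
print.lrt_result <- function(x, ...) {
  comps <- paste(sprintf("%.2f*chisq(%d)", x$reference$weights,
                         x$reference$df), collapse = " + ")
  cat(sprintf("LRT: Lambda = %.4f, p = %s  [ref: %s]\n", x$statistic,
              format_pvalue(x$p_value), comps))
  invisible(x)
}

#' @export
print.two_stage_report <- function(x, ...) {
  cat("Two-stage GxE testing report\n")
  cat(sprintf("  polygenic: lnL = %.4f, h2 = %s\n", x$polygenic$loglik,
              format_h2(x$polygenic$h2, x$polygenic$se_h2)))
  cat(sprintf("  full GxE:  lnL = %.4f\n", x$full$loglik))
  cat(sprintf("  stage 1:   Lambda = %.4f, p = %s\n", x$stage1$statistic,
              format_pvalue(x$stage1$p_value)))
  cat(sprintf("  model used: %s%s\n", x$model_used,
              if (length(x$dropped))
                paste0(" (dropped: ", paste(x$dropped, collapse = ", "), ")")
              else ""))
  for (p in names(x$stage2))
    cat(sprintf("  stage 2 %-9s Lambda = %8.4f, p = %s\n", paste0(p, ":"),
                x$stage2[[p]]$statistic,
                format_pvalue(x$stage2[[p]]$p_value)))
  invisible(x)
}
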