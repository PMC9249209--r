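#' Fitted stepped-wedge mixed model
#'
#' Objects of class `sw_fit` are returned by [sw_lmm], [sw_glmm],
#' [sw_model] and [run_analysis]. They carry the fixed-effect estimates
#' and covariance, random-effect SDs, the (approximate) log-likelihood,
#' convergence/boundary flags and, when an `intervention` term is present,
#' the headline effect on the odds-ratio or geometric-mean-ratio scale
#' with its Wald 95% CI.
#'
#' @param x,object an `sw_fit`.
#' @param ... unused.
#' @name sw_fit
NULL

#' @rdname sw_fit
#' @export
print.sw_fit <- function(x, ...) {
  cat("Stepped-wedge mixed model fit (", x$method, ", ", x$family, ")\n", sep = "")
  cat("  n =", x$n_used, " log-likelihood =", format(x$loglik, digits = 8), "\n")
  sds <- paste(names(x$re_sd), format(x$re_sd, digits = 4), collapse = ", ")
  cat("  random-effect SD:", sds,
      if (isTRUE(x$boundary)) "(boundary: effectively zero)" else "", "\n")
  if (!x$converged) cat("  WARNING: optimiser did not converge\n")
  if (!is.null(x$effect))
    cat(sprintf("  %s (%s): %.3f [95%% CI %.3f, %.3f]\n", x$effect$term,
                x$effect$scale, x$effect$estimate, x$effect$ci_low,
                x$effect$ci_high))
  invisible(x)
}

#' @rdname sw_fit
#' @export
summary.sw_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- data.frame(estimate = object$coefficients, se = se, z = z,
                    p = 2 * stats::pnorm(-abs(z)),
                    ci_low = object$coefficients - 1.96 * se,
                    ci_high = object$coefficients + 1.96 * se)
  out <- list(coefficients = tab, re_sd = object$re_sd, method = object$method,
              family = object$family, n_used = object$n_used,
              loglik = object$loglik, converged = object$converged,
              boundary = object$boundary, effect = object$effect)
  class(out) <- "summary.sw_fit"
  out
}

#' @export
print.summary.sw_fit <- function(x, ...) {
  cat("Fixed effects (", x$method, "):\n", sep = "")
  print(round(x$coefficients, 5))
  cat("Random-effect SD:", paste(names(x$re_sd), format(x$re_sd, digits = 4),
                                 collapse = ", "), "\n")
  if (!is.null(x$effect))
    cat(sprintf("%s: %.3f [%.3f, %.3f] (%s scale)\n", x$effect$term,
                x$effect$estimate, x$effect$ci_low, x$effect$ci_high,
                x$effect$scale))
  invisible(x)
}

#' @rdname sw_fit
#' @export
coef.sw_fit <- function(object, ...) object$coefficients

#' @rdname sw_fit
#' @export
vcov.sw_fit <- function(object, ...) object$vcov

#' @rdname sw_fit
#' @param parm coefficients to include (default all).
#' @param level confidence level.
#' @param exponentiate return ratio-scale bounds?
#' @export
confint.sw_fit <- function(object, parm = NULL, level = 0.95,
                           exponentiate = FALSE, ...) {
  se <- sqrt(diag(object$vcov))
  est <- object$coefficients
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(low = est - z * se, high = est + z * se)
  if (exponentiate) out <- exp(out)
  if (!is.null(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @rdname sw_fit
#' @export
logLik.sw_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) +
              length(object$re_sd), class = "logLik")
}

#' @rdname sw_fit
#' @param newX design matrix for prediction (defaults to refitting values);
#'   columns must match the coefficient names.
#' @param type `"link"` (linear predictor, fixed effects at the typical
#'   cluster, u = 0) or `"response"`.
#' @export
predict.sw_fit <- function(object, newX = NULL, type = c("link", "response"),
                           ...) {
  type <- match.arg(type)
  if (is.null(newX)) {
    if (type == "response" && object$family == "binomial") return(object$fitted)
    if (type == "link" && object$family == "gaussian") return(object$fitted)
    if (object$family == "binomial") return(stats::qlogis(object$fitted))
    return(object$fitted)
  }
  newX <- as.matrix(newX)
  eta <- drop(newX[, names(object$coefficients), drop = FALSE] %*%
                object$coefficients)
  if (type == "response" && object$family == "binomial") stats::plogis(eta)
  else eta
}

#' @rdname sw_fit
#' @export
residuals.sw_fit <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted
  if (type == "pearson" && object$family == "binomial")
    r <- r / sqrt(pmax(object$fitted * (1 - object$fitted), 1e-12))
  r
}

#' Formula interface to the stepped-wedge mixed models
#'
#' Convenience front-end that builds the fixed-effects design matrix from a
#' formula and dispatches to [sw_lmm] (gaussian) or [sw_glmm] (binomial).
#' The random structure is a cluster intercept by default; supply
#' `random = ~ term` to add a random slope (binomial Laplace fits only).
#'
#' @param formula model formula for the fixed effects.
#' @param data data frame.
#' @param cluster one-sided formula or column name giving the cluster id.
#' @param family `"gaussian"` or `"binomial"`.
#' @param weights optional per-row weights.
#' @param random `~1` (default) or a one-sided formula naming one extra
#'   random-slope variable.
#' @param ... passed to the engine ([sw_lmm] / [sw_glmm]).
#' @return an [`sw_fit`][print.sw_fit].
#' @export
sw_model <- function(formula, data, cluster = ~site,
                     family = c("binomial", "gaussian"), weights = NULL,
                     random = ~1, ...) {
  family <- match.arg(family)
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  X <- stats::model.matrix(formula, mf)
  colnames(X)[colnames(X) == "(Intercept)"] <- "intercept"
  y <- stats::model.response(mf)
  used <- as.integer(rownames(mf))
  cl_var <- if (inherits(cluster, "formula")) all.vars(cluster) else cluster
  cl <- data[[cl_var]][used]
  w <- if (!is.null(weights)) weights[used] else NULL
  if (family == "gaussian") {
    sw_lmm(X, y, cl, weights = w, ...)
  } else {
    rv <- all.vars(random)
    Z <- if (length(rv)) data[[rv]][used] else NULL
    sw_glmm(X, y, cl, weights = w, Z = Z, ...)
  }
}
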