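# Simulation harness: operating characteristics (type-I error, bias,
# coverage) of the primary safety model under the trial's design.

#' Parameter-recovery simulation study
#'
#' Simulates `reps` datasets from the parametric generator with the
#' intervention log odds ratio set to `true_log_or`, fits the requested
#' analysis model to each, and aggregates rejection rate (two-sided Wald
#' test of no intervention effect at 5%), bias of the log odds ratio and
#' 95% CI coverage of the truth, each with its Monte-Carlo standard
#' error. Non-converged replicates are excluded and counted; more than
#' 10% of them aborts with diagnostics.
#'
#' @param design an [sw_design].
#' @param params an [sw_cohort_params]; its intervention log OR is
#'   overridden by `true_log_or`.
#' @param true_log_or the simulation truth.
#' @param reps number of replicates.
#' @param n presentations per replicate.
#' @param seed integer seed (replicate r uses `seed + r`).
#' @param code,method analysis model and estimation method per replicate.
#' @return list of class `sw_simstudy` with `reps_used`, `n_nonconverged`,
#'   `reject_rate`, `bias`, `coverage`, `mean_ci_width` (log-OR scale) and
#'   `mc_se` for each metric, plus the per-replicate `estimates`.
#' @export
recovery_study <- function(design, params = sw_cohort_params(), true_log_or = 0,
                           reps = 500L, n = 31492L, seed = 1L, code = "A",
                           method = "Laplace") {
  params$safety_intervention_log_or <- true_log_or
  est <- se <- rep(NA_real_, reps)
  conv <- logical(reps)
  for (r in seq_len(reps)) {
    dat <- generate_parametric(design, params, n = n, seed = seed + r)
    fit <- tryCatch(run_analysis(dat, design, code, outcome = "safety",
                                 method = method),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged ||
        !is.finite(fit$effect$se_log) || fit$effect$se_log <= 0) next
    conv[r] <- TRUE
    est[r] <- fit$effect$log_estimate
    se[r] <- fit$effect$se_log
  }
  n_bad <- sum(!conv)
  if (n_bad > 0.1 * reps)
    stop(n_bad, " of ", reps, " replicates failed to converge", call. = FALSE)
  est <- est[conv]; se <- se[conv]
  m <- length(est)
  z <- (est - 0) / se
  reject <- mean(abs(z) > stats::qnorm(0.975))
  cover <- mean(abs(est - true_log_or) <= stats::qnorm(0.975) * se)
  bias <- mean(est) - true_log_or
  out <- list(reps_used = m, n_nonconverged = n_bad,
              true_log_or = true_log_or,
              reject_rate = reject, bias = bias, coverage = cover,
              mean_ci_width = mean(2 * stats::qnorm(0.975) * se),
              mc_se = c(reject_rate = sqrt(reject * (1 - reject) / m),
                        bias = stats::sd(est) / sqrt(m),
                        coverage = sqrt(cover * (1 - cover) / m)),
              estimates = data.frame(log_or = est, se = se))
  class(out) <- "sw_simstudy"
  out
}

#' Null simulation study (type-I error and bias)
#'
#' [recovery_study] at a true log odds ratio of exactly 0; the rejection
#' rate is then the type-I error of the two-sided 5% Wald test.
#'
#' @inheritParams recovery_study
#' @export
simulate_null_study <- function(design, params = sw_cohort_params(),
                                reps = 500L, n = 31492L, seed = 1L,
                                code = "A", method = "Laplace") {
  if (params$safety_intervention_log_or != 0)
    stop("a null study requires safety_intervention_log_or = 0", call. = FALSE)
  recovery_study(design, params, true_log_or = 0, reps = reps, n = n,
                 seed = seed, code = code, method = method)
}

#' @export
print.sw_simstudy <- function(x, ...) {
  cat("Simulation study:", x$reps_used, "replicates used (",
      x$n_nonconverged, "non-converged ), truth log OR =", x$true_log_or, "\n")
  cat(sprintf("  rejection rate %.3f (mc se %.3f)\n", x$reject_rate,
              x$mc_se["reject_rate"]))
  cat(sprintf("  bias           %+.4f (mc se %.4f)\n", x$bias,
              x$mc_se["bias"]))
  cat(sprintf("  coverage       %.3f (mc se %.3f)\n", x$coverage,
              x$mc_se["coverage"]))
  invisible(x)
}
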