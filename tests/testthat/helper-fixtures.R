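# Shared fixtures: all test data are generated in code.

default_design <- function() sw_design()

# small binary-outcome instance with a known random-intercept structure,
# used for quadrature and engine tests
toy_glmm_data <- function(n = 400, C = 5, sigma_u = 0.8, beta = c(-1, 0.7, 0.3),
                          seed = 1) {
  set.seed(seed)
  cl <- sample(paste0("c", seq_len(C)), n, replace = TRUE)
  u <- stats::setNames(rnorm(C, 0, sigma_u), paste0("c", seq_len(C)))
  z <- rbinom(n, 1, 0.5)
  x <- rnorm(n)
  eta <- beta[1] + beta[2] * z + beta[3] * x + u[cl]
  y <- rbinom(n, 1, plogis(eta))
  list(X = cbind(intercept = 1, intervention = z, x = x), y = y, cl = cl)
}

# a modest synthetic trial with a common event and a real intervention
# effect, cheap enough for repeated refits (tipping, augmentation shrinkage)
toy_trial <- function(n = 6000, rate = 0.03, log_or = 0.9, seed = 3,
                      design = sw_design()) {
  params <- sw_cohort_params(safety_baseline_logit = qlogis(rate),
                             safety_intervention_log_or = log_or)
  generate_parametric(design, params, n = n, seed = seed)
}

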