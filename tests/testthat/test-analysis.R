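test_that("the model catalogue matches its published structure", {
  A <- model_spec("A")
  expect_equal(A[c("population", "timing", "time_trend", "season", "exposure",
                   "random")],
               list(population = "full", timing = "actual",
                    time_trend = "linear", season = "on", exposure = "none",
                    random = "intercept"))
  B <- model_spec("B")
  expect_equal(B$population, "calendar_matched")
  expect_equal(B$time_trend, "none")
  expect_equal(B$season, "off")
  expect_equal(model_spec("C")$random, "intercept+intervention")
  expect_equal(model_spec("D")$population, "randomisation_phase")
  expect_equal(model_spec("E")$timing, "planned")
  expect_equal(model_spec("F")$random, "intercept+time")
  expect_equal(model_spec("G")$exposure, "linear")
  expect_equal(model_spec("H")$time_trend, "spline")
  I <- model_spec("I")
  expect_equal(I$time_trend, "spline"); expect_equal(I$exposure, "spline")
  J <- model_spec("J")
  expect_equal(J$time_trend, "categorical_3mo"); expect_equal(J$season, "off")
  K <- model_spec("K")
  expect_equal(K$time_trend, "categorical_3mo"); expect_equal(K$exposure, "spline")
  expect_error(model_spec("Z"))
})

test_that("adjustment methods carry the published covariate lists", {
  expect_equal(adjustment_spec("none")$covariates, character(0))
  expect_equal(adjustment_spec("AFD")$covariates, c("age", "sex", "simd"))
  amc <- adjustment_spec("AMC")$covariates
  expect_length(amc, 13)
  expect_true(all(c("hx_ihd", "hx_mi", "hx_cvd", "hx_diabetes", "hx_pci",
                    "hx_cabg", "hx_aspirin", "hx_lipid", "hx_betablocker",
                    "hx_acei", "age", "sex", "simd") %in% amc))
  expect_equal(adjustment_spec("APS")$covariates, amc)
  expect_equal(adjustment_spec("IPTW")$covariates, amc)
})

test_that("design assembly produces the columns each model prescribes", {
  des <- default_design()
  dat <- toy_trial(n = 4000, seed = 31)
  bA <- build_design(dat, des, "A")
  expect_setequal(colnames(bA$X),
                  c("intercept", "intervention", "seasonSpring",
                    "seasonSummer", "seasonAutumn", "ctime"))
  bJ <- build_design(dat, des, "J")
  expect_false(any(grepl("season", colnames(bJ$X))))
  expect_equal(sum(grepl("^period_", colnames(bJ$X))), 7)  # 8 bins, 1 reference
  bB <- build_design(dat, des, "B")
  expect_false(any(grepl("season|ctime|period", colnames(bB$X))))
  expect_setequal(colnames(bB$X), c("intercept", "intervention"))
  bG <- build_design(dat, des, "G")
  expect_true("exposure" %in% colnames(bG$X))
  bH <- build_design(dat, des, "H")
  expect_equal(sum(grepl("^time_s", colnames(bH$X))), 4)
  # centred time averages ~0 over the population
  expect_lt(abs(mean(bA$X[, "ctime"])), 10)
})

test_that("IPTW weights follow the inverse-probability formula", {
  # w = Z/p + (1-Z)/(1-p): spot identities
  expect_equal(1 / 0.5 , 2)           # p = 0.5, either arm
  p <- 0.2; expect_equal(1 / (1 - p), 1.25)  # control record
  des <- default_design()
  dat <- toy_trial(n = 5000, seed = 32)
  ps <- estimate_propensity(dat, des)
  w_manual <- ps$Z / ps$p + (1 - ps$Z) / (1 - ps$p)
  expect_equal(ps$w, w_manual)
  expect_true(all(ps$w >= 1))
  expect_true(all(ps$p > 0 & ps$p < 1))
  expect_error(estimate_propensity(dat[derive_variables(dat, des)$condition ==
                                         "control", ], des), "both conditions")
})

test_that("covariates independent of condition give a near-flat propensity", {
  des <- default_design()
  dat <- toy_trial(n = 8000, rate = 0.05, log_or = 0.5, seed = 33)
  ps <- estimate_propensity(dat, des)
  # logit propensity varies far less than condition assignment itself
  expect_lt(sd(ps$logit_p), 0.35)
  fit_none <- run_analysis(dat, des, "A", "none", outcome = "safety")
  fit_aps <- run_analysis(dat, des, "A", "APS", outcome = "safety")
  expect_lt(abs(fit_aps$effect$log_estimate - fit_none$effect$log_estimate),
            0.1)
})

test_that("group-constant weights leave the odds ratio unchanged", {
  set.seed(34)
  n <- 3000
  cl <- sample(paste0("s", 1:7), n, TRUE)
  z <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-2 + 0.6 * z))
  X <- cbind(intercept = 1, intervention = z)
  w <- ifelse(z == 1, 1.7, 3.1)
  f_u <- sw_glmm(X, y, cl, method = "Laplace")
  f_w <- sw_glmm(X, y, cl, weights = w, method = "Laplace")
  expect_lt(abs(coef(f_u)[["intervention"]] - coef(f_w)[["intervention"]]),
            1e-3)
})

test_that("an analysis grid runs end-to-end with labelled results", {
  des <- default_design()
  dat <- toy_trial(n = 4000, rate = 0.05, seed = 35)
  res <- run_suite(dat, des, codes = c("A", "B", "D", "G", "J"),
                   adjustments = c("none", "AFD", "IPTW"), outcome = "safety")
  expect_length(res, 15)
  expect_true(all(!vapply(res, is.null, logical(1))))
  labs <- vapply(res, function(f) paste(f$analysis$code, f$analysis$adjustment,
                                        sep = "."), character(1))
  expect_equal(unname(labs), names(res))
  tab <- forest_table(res)
  expect_equal(nrow(tab), 15)
  expect_true(all(tab$scale == "OR"))
  expect_true(all(tab$ci_low <= tab$estimate & tab$estimate <= tab$ci_high))
  # LOS arm of the same grid reports geometric mean ratios
  res_los <- run_suite(dat, des, codes = "A", adjustments = "none",
                       outcome = "los")
  tab2 <- forest_table(c(res, res_los))
  expect_setequal(unique(tab2$scale), c("OR", "GMR"))
})

test_that("the full model catalogue including random-slope models fits", {
  des <- default_design()
  dat <- toy_trial(n = 3000, rate = 0.05, seed = 36)
  for (code in c("C", "E", "F", "H", "I", "K")) {
    f <- run_analysis(dat, des, code, outcome = "safety")
    expect_s3_class(f, "sw_fit")
    expect_true(is.finite(f$effect$estimate))
  }
  # as-randomised timing changes the intervention indicator where
  # planned and actual crossovers differ
  bA <- build_design(dat, des, "A")
  bE <- build_design(dat, des, "E")
  expect_gt(sum(bA$X[, "intervention"] != bE$X[, "intervention"]), 0)
})

test_that("null data recover an odds ratio near 1 in the calendar-matched model", {
  des <- default_design()
  params <- sw_cohort_params(safety_baseline_logit = qlogis(0.05))
  dat <- generate_parametric(des, params, n = 8000, seed = 37)
  f <- run_analysis(dat, des, "B", outcome = "safety")
  expect_true(f$effect$ci_low < 1 & 1 < f$effect$ci_high)
})

test_that("risk differences match the homogeneous closed form and null/sign rules", {
  des <- default_design()
  dat <- toy_trial(n = 6000, rate = 0.05, log_or = 0.7, seed = 38)
  f <- run_analysis(dat, des, "B", outcome = "safety")
  rd <- approximate_risk_difference(f)
  # homogeneous population: AME equals p1 - p0 with logit p1 = logit p0 + logOR
  b <- coef(f)
  p0 <- plogis(b[["intercept"]])
  p1 <- plogis(b[["intercept"]] + b[["intervention"]])
  expect_equal(rd[["rd"]], 100 * (p1 - p0), tolerance = 1e-8)
  expect_equal(sign(rd[["rd"]]), sign(b[["intervention"]]))
  # forcing a null effect gives RD 0
  f0 <- f
  f0$coefficients[["intervention"]] <- 0
  expect_equal(approximate_risk_difference(f0)[["rd"]], 0)
})

test_that("adjustment corrects confounding drift better than no adjustment", {
  des <- default_design()
  params <- sw_cohort_params(safety_baseline_logit = qlogis(0.05),
                             safety_intervention_log_or = 0,
                             safety_age_log_or = 0.06,
                             confounding_drift = 0.012)
  err <- matrix(NA_real_, 30, 4,
                dimnames = list(NULL, c("none", "AMC", "APS", "IPTW")))
  for (r in 1:30) {
    dat <- generate_parametric(des, params, n = 4000, seed = 700 + r)
    for (adj in colnames(err)) {
      f <- run_analysis(dat, des, "B", adj, outcome = "safety")
      err[r, adj] <- abs(f$effect$log_estimate)
    }
  }
  expect_lt(mean(err[, "AMC"]), mean(err[, "none"]))
  expect_lt(mean(err[, "APS"]), mean(err[, "none"]))
  expect_lt(mean(err[, "IPTW"]), mean(err[, "none"]))
})
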