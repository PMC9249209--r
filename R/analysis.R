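# Declarative catalogue of the sensitivity-analysis models (codes A-K) and
# covariate-adjustment methods, and the machinery that runs any
# (model, adjustment) pair end-to-end on a trial dataset.

#' Model specification catalogue (analyses A-K)
#'
#' Returns the declarative specification of one of the eleven analysis
#' models: the pre-specified set (A primary; B calendar-matched
#' before/after with no time or season terms; C random intervention
#' effect; D randomisation phase only; E as-randomised timing) and the
#' post-hoc set (F random time slope; G linear exposure time; H cubic
#' spline time trend; I spline time + spline exposure; J categorical
#' 3-monthly time with no season terms; K categorical time + spline
#' exposure).
#'
#' @param code single letter `"A"`..`"K"`.
#' @return list with fields `code`, `population` (full /
#'   calendar_matched / randomisation_phase), `timing` (actual /
#'   planned), `time_trend` (linear / spline / categorical_3mo / none),
#'   `season` (on/off), `exposure` (none / linear / spline) and `random`
#'   (intercept / intercept+intervention / intercept+time).
#' @export
model_spec <- function(code) {
  code <- match.arg(toupper(code), LETTERS[1:11])
  base <- list(code = code, population = "full", timing = "actual",
               time_trend = "linear", season = "on", exposure = "none",
               random = "intercept")
  mods <- switch(code,
    A = list(),
    B = list(population = "calendar_matched", time_trend = "none", season = "off"),
    C = list(random = "intercept+intervention"),
    D = list(population = "randomisation_phase"),
    E = list(timing = "planned"),
    F = list(random = "intercept+time"),
    G = list(exposure = "linear"),
    H = list(time_trend = "spline"),
    I = list(time_trend = "spline", exposure = "spline"),
    J = list(time_trend = "categorical_3mo", season = "off"),
    K = list(time_trend = "categorical_3mo", season = "off", exposure = "spline"))
  base[names(mods)] <- mods
  base
}

#' Covariate-adjustment specification
#'
#' The four adjustment methods: `AFD` enters the key demographics (age,
#' sex, deprivation quintile) directly; `AMC` enters the full 13-variable
#' list (ten history flags plus demographics) directly; `APS` adds the
#' logit of a mixed-model propensity score as a single linear column;
#' `IPTW` weights the fit by the inverse probability of the condition
#' actually experienced.
#'
#' @param method one of `"none"`, `"AFD"`, `"AMC"`, `"APS"`, `"IPTW"`.
#' @return list with `method` and `covariates`.
#' @export
adjustment_spec <- function(method = c("none", "AFD", "AMC", "APS", "IPTW")) {
  method <- match.arg(method)
  covs <- switch(method,
                 none = character(0),
                 AFD = c("age", "sex", "simd"),
                 c(hx_cols, "age", "sex", "simd"))
  list(method = method, covariates = covs)
}

dummy_cols <- function(f, prefix, ref = NULL) {
  f <- droplevels(factor(f))
  if (!is.null(ref) && ref %in% levels(f)) f <- stats::relevel(f, ref)
  if (nlevels(f) < 2L) return(NULL)
  m <- stats::model.matrix(~f)[, -1, drop = FALSE]
  colnames(m) <- paste0(prefix, sub("^f", "", colnames(m)))
  m
}

# spline for exposure time: many exact zeros, so interior knots are placed
# at quantiles of the positive exposures
exposure_spline <- function(x, n_knots = 3L) {
  pos <- x[x > 0]
  if (length(unique(pos)) <= n_knots)
    stop("too few distinct positive exposure times for a spline", call. = FALSE)
  knots <- unname(stats::quantile(pos, seq_len(n_knots) / (n_knots + 1)))
  b <- splines::ns(x, knots = knots, Boundary.knots = range(x))
  colnames(b) <- paste0("exposure_s", seq_len(ncol(b)))
  unclass(b)[, , drop = FALSE]
}

#' Assemble design matrices for an analysis model
#'
#' Applies the model's population filter and crossover timing, derives the
#' analysis variables and assembles the fixed-effects matrix: intercept,
#' intervention indicator, the time trend as specified (centred linear /
#' natural cubic spline with 3 interior knots / categorical 3-monthly
#' periods with the first period as reference), season dummies (Winter
#' reference), exposure-time terms, and any adjustment covariates (age
#' centred at the population mean). Dummy columns that are constant in the
#' filtered population (e.g. seasons absent from a restricted phase) are
#' dropped. Returns everything a fitting engine needs.
#'
#' @param data trial data frame in the standard schema.
#' @param design an [sw_design].
#' @param spec a [model_spec] (or a code letter).
#' @param adjustment an [adjustment_spec] (or a method name).
#' @param ps optional propensity-score result from [estimate_propensity]
#'   computed on the same filtered population (required for APS/IPTW).
#' @return list with `X`, `data` (the filtered, derived rows), `cluster`,
#'   `weights`, `random` and bookkeeping fields.
#' @export
build_design <- function(data, design, spec, adjustment = "none", ps = NULL) {
  if (is.character(spec)) spec <- model_spec(spec)
  if (is.character(adjustment)) adjustment <- adjustment_spec(adjustment)
  d <- derive_variables(data, design, timing = spec$timing)
  d <- switch(spec$population,
              full = d,
              calendar_matched = filter_calendar_matched(d, design),
              randomisation_phase = filter_randomisation_phase(d, design))
  if (nrow(d) == 0L) stop("analysis population is empty", call. = FALSE)
  n <- nrow(d)
  parts <- list(intercept = matrix(1, n, 1, dimnames = list(NULL, "intercept")),
                intervention = matrix(as.integer(d$condition == "intervention"),
                                      n, 1, dimnames = list(NULL, "intervention")))
  if (spec$season == "on")
    parts$season <- dummy_cols(d$season, "season", ref = "Winter")
  mid <- (min(d$day) + max(d$day)) / 2
  if (spec$time_trend == "linear") {
    parts$time <- matrix(centred_time(d$day, mid), n, 1,
                         dimnames = list(NULL, "ctime"))
  } else if (spec$time_trend == "spline") {
    b <- time_spline_basis(d$day, 3L)
    colnames(b) <- paste0("time_", colnames(b))
    parts$time <- b
  } else if (spec$time_trend == "categorical_3mo") {
    period <- pmin((d$day - design$study_start_day) %/% 91L, 7L)
    parts$time <- dummy_cols(period, "period_")
  }
  if (spec$exposure == "linear") {
    parts$exposure <- matrix(d$exposure, n, 1, dimnames = list(NULL, "exposure"))
  } else if (spec$exposure == "spline") {
    parts$exposure <- exposure_spline(d$exposure, 3L)
  }
  weights <- NULL
  if (length(adjustment$covariates)) {
    miss <- setdiff(adjustment$covariates, names(d))
    if (length(miss)) stop("unknown adjustment covariates: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    A <- as.matrix(d[, adjustment$covariates, drop = FALSE])
    A[, "age"] <- A[, "age"] - mean(A[, "age"])
    parts$adjust <- A
  }
  if (adjustment$method %in% c("APS", "IPTW")) {
    if (is.null(ps)) stop("APS/IPTW adjustment needs a propensity-score result",
                          call. = FALSE)
    if (length(ps$p) != n)
      stop("propensity scores were not estimated on this analysis population",
           call. = FALSE)
    if (adjustment$method == "APS") {
      parts$adjust <- matrix(ps$logit_p, n, 1, dimnames = list(NULL, "logit_ps"))
    } else {
      parts$adjust <- NULL
      weights <- ps$w
    }
  }
  X <- do.call(cbind, parts[!vapply(parts, is.null, logical(1))])
  keep <- apply(X, 2, function(col) stats::var(col) > 0) | colnames(X) == "intercept"
  X <- X[, keep, drop = FALSE]
  list(X = X, data = d, cluster = d$site, weights = weights,
       random = spec$random, spec = spec, adjustment = adjustment,
       enrolment_mid = mid)
}

#' Mixed-model propensity score and IPTW weights
#'
#' Fits a random-intercept (site) logistic mixed model of the condition
#' actually experienced on the adjustment covariates, by the Laplace
#' method, and returns per-patient propensities (trimmed away from 0/1),
#' their logits and inverse-probability-of-treatment weights
#' `w = Z/p + (1-Z)/(1-p)`. For restricted populations
#' (calendar-matched, randomisation-phase) the score must be re-estimated
#' on the restricted data: pass those rows here.
#'
#' @param data derived or raw trial rows of the analysis population.
#' @param design an [sw_design].
#' @param covariates covariate names (default the 13-variable list).
#' @param timing crossover timing defining the condition.
#' @param trim propensities are clamped to `[trim, 1 - trim]`.
#' @param truncate_weights optional upper quantile (e.g. 0.99) at which
#'   IPTW weights are truncated; default off.
#' @return list of class `sw_ps` with `p`, `logit_p`, `w`, `Z`, `fit`.
#' @export
estimate_propensity <- function(data, design,
                                covariates = adjustment_spec("AMC")$covariates,
                                timing = "actual", trim = 1e-6,
                                truncate_weights = NULL) {
  d <- derive_variables(data, design, timing = timing)
  Z <- as.integer(d$condition == "intervention")
  if (length(unique(Z)) < 2L)
    stop("both conditions must be present to estimate a propensity score",
         call. = FALSE)
  A <- as.matrix(d[, covariates, drop = FALSE])
  if ("age" %in% colnames(A)) A[, "age"] <- A[, "age"] - mean(A[, "age"])
  X <- cbind(intercept = 1, A)
  fit <- sw_glmm(X, Z, d$site, method = "Laplace")
  p <- pmin(pmax(fit$fitted, trim), 1 - trim)
  w <- Z / p + (1 - Z) / (1 - p)
  if (!is.null(truncate_weights))
    w <- pmin(w, stats::quantile(w, truncate_weights))
  structure(list(p = p, logit_p = stats::qlogis(p), w = w, Z = Z, fit = fit),
            class = "sw_ps")
}

#' Run one (analysis, adjustment) pair end-to-end
#'
#' Applies the model's population filter and timing, estimates the
#' propensity score on the filtered population when needed, assembles the
#' design, fits the linear mixed model (length of stay, log-transformed;
#' effect reported as a geometric mean ratio) or the logistic mixed model
#' (safety event; odds ratio), and attaches the analysis label.
#'
#' @inheritParams build_design
#' @param code analysis code `"A"`..`"K"`.
#' @param adjustment `"none"`, `"AFD"`, `"AMC"`, `"APS"` or `"IPTW"`.
#' @param outcome `"safety"` or `"los"`.
#' @param method estimation method for safety fits: `"Laplace"` (default,
#'   the switch used for post-hoc fits) or `"AGQ"`.
#' @param n_nodes quadrature nodes for `"AGQ"`.
#' @param ... further arguments to [sw_glmm] (e.g. `robust`).
#' @return an [`sw_fit`][print.sw_fit] with an `analysis` field and the
#'   design matrix attached.
#' @export
run_analysis <- function(data, design, code, adjustment = "none",
                         outcome = c("safety", "los"),
                         method = c("Laplace", "AGQ"), n_nodes = 25L, ...) {
  outcome <- match.arg(outcome)
  method <- match.arg(method)
  spec <- model_spec(code)
  adj <- adjustment_spec(adjustment)
  if (outcome == "los") {
    data <- data[!is.na(data$los_hours), , drop = FALSE]
  }
  ps <- NULL
  if (adj$method %in% c("APS", "IPTW")) {
    # re-estimate the score on the analysis population
    dpop <- derive_variables(data, design, timing = spec$timing)
    dpop <- switch(spec$population,
                   full = dpop,
                   calendar_matched = filter_calendar_matched(dpop, design),
                   randomisation_phase = filter_randomisation_phase(dpop, design))
    ps <- estimate_propensity(dpop[, dataset_cols], design,
                              covariates = adj$covariates,
                              timing = spec$timing)
  }
  b <- build_design(data, design, spec, adj, ps = ps)
  fit <- tryCatch({
    if (outcome == "los") {
      sw_lmm(b$X, log(b$data$los_hours), b$cluster, weights = b$weights)
    } else {
      Z <- switch(b$random,
                  intercept = NULL,
                  `intercept+intervention` = b$X[, "intervention"],
                  `intercept+time` = centred_time(b$data$day, b$enrolment_mid) / 365.25)
      sw_glmm(b$X, b$data$safety_event, b$cluster, weights = b$weights, Z = Z,
              method = method, n_nodes = n_nodes, ...)
    }
  }, error = function(e) {
    stop("analysis ", spec$code, "/", adj$method, " failed: ",
         conditionMessage(e), call. = FALSE)
  })
  fit$analysis <- list(code = spec$code, adjustment = adj$method,
                       outcome = outcome, population = spec$population,
                       timing = spec$timing)
  fit$X <- b$X
  fit$ps <- ps
  fit
}

#' Run a grid of analyses
#'
#' Enumerates all requested (code, adjustment) pairs on one dataset and
#' outcome; non-converged fits are kept and flagged, fits that error are
#' recorded as NULL with a message.
#'
#' @inheritParams run_analysis
#' @param codes analysis codes to run.
#' @param adjustments adjustment methods to run.
#' @return named list of [`sw_fit`][print.sw_fit]s
#'   (`"<code>.<adjustment>"`).
#' @export
run_suite <- function(data, design, codes = LETTERS[1:11],
                      adjustments = c("none", "AFD", "AMC", "APS", "IPTW"),
                      outcome = "safety", ...) {
  out <- list()
  for (code in codes) for (adj in adjustments) {
    lab <- paste(code, adj, sep = ".")
    out[[lab]] <- tryCatch(
      run_analysis(data, design, code, adj, outcome = outcome, ...),
      error = function(e) {
        message(lab, ": ", conditionMessage(e))
        NULL
      })
  }
  out
}

#' Approximate risk difference from a safety-model fit
#'
#' Average marginal effect on the probability scale: the mean over the
#' analysis population of the model probability with the intervention
#' indicator set to 1 minus that with it set to 0 (random effects at their
#' typical value, u = 0), with a delta-method Wald CI. Reported in
#' percentage points.
#'
#' @param fit an [`sw_fit`][print.sw_fit] from [run_analysis] on the
#'   safety outcome (the design matrix travels with it).
#' @param X optional design matrix override.
#' @return named vector `c(rd, ci_low, ci_high)` in %.
#' @export
approximate_risk_difference <- function(fit, X = fit$X) {
  if (fit$family != "binomial")
    stop("risk differences are defined for safety-outcome fits", call. = FALSE)
  if (is.null(X)) stop("fit carries no design matrix", call. = FALSE)
  beta <- fit$coefficients
  X <- X[, names(beta), drop = FALSE]
  X1 <- X0 <- X
  X1[, "intervention"] <- 1
  X0[, "intervention"] <- 0
  p1 <- stats::plogis(drop(X1 %*% beta))
  p0 <- stats::plogis(drop(X0 %*% beta))
  rd <- mean(p1 - p0)
  g <- colMeans((p1 * (1 - p1)) * X1 - (p0 * (1 - p0)) * X0)
  se <- sqrt(drop(t(g) %*% fit$vcov %*% g))
  ci <- wald_ci(rd, max(se, 1e-12))
  c(rd = 100 * rd, ci_low = 100 * unname(ci["low"]),
    ci_high = 100 * unname(ci["high"]))
}

#' Forest-plot table of effect estimates
#'
#' Collects fitted analyses into a plot-ready table ordered by code then
#' adjustment, with the effect scale (OR or GMR) per row and a divergence
#' flag marking rows whose 95% CI does not overlap that of the reference
#' (code A, unadjusted, same outcome) result.
#'
#' @param results list of [`sw_fit`][print.sw_fit]s from [run_analysis] /
#'   [run_suite] (NULL entries are skipped).
#' @return data frame with columns `label`, `code`, `adjustment`, `scale`,
#'   `estimate`, `ci_low`, `ci_high`, `n_used`, `converged`, `divergent`.
#' @export
forest_table <- function(results) {
  results <- Filter(Negate(is.null), results)
  if (!length(results)) stop("no results to tabulate", call. = FALSE)
  rows <- lapply(results, function(f) {
    a <- f$analysis %||% list(code = NA, adjustment = NA, outcome = f$family)
    data.frame(label = paste0(a$code, ".", a$adjustment),
               code = a$code, adjustment = a$adjustment,
               scale = f$effect$scale, estimate = f$effect$estimate,
               ci_low = f$effect$ci_low, ci_high = f$effect$ci_high,
               n_used = f$n_used, converged = f$converged,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  adj_order <- c("none", "AFD", "AMC", "APS", "IPTW")
  tab <- tab[order(tab$code, match(tab$adjustment, adj_order)), , drop = FALSE]
  ref <- which(tab$code == "A" & tab$adjustment == "none")
  if (!length(ref)) ref <- which(tab$code == "A")
  tab$divergent <- FALSE
  if (length(ref)) {
    r <- tab[ref[1], ]
    tab$divergent <- tab$ci_low > r$ci_high | tab$ci_high < r$ci_low
  }
  rownames(tab) <- NULL
  tab
}
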