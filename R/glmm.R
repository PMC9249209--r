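# Mixed-model estimation machinery: random-intercept linear mixed model by
# profiled REML, and a logistic mixed model whose marginal likelihood is
# approximated by the Laplace method or adaptive Gauss-Hermite quadrature.
# Clusters are hospital sites (few clusters, very large cluster sizes), so
# everything is organised around per-cluster aggregation of row-level terms.

log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

inv_logit <- function(x) 1 / (1 + exp(-x))

# per-cluster sums of v for rows already sorted by cluster: `ends` holds the
# last row index of each cluster block (one cumsum pass, no per-group copies)
group_sums <- function(v, ends) {
  cs <- cumsum(v)[ends]
  c(cs[1], diff(cs))
}

#' Natural cubic spline basis for a time trend
#'
#' Natural cubic spline basis with `n_knots` interior knots at equally
#' spaced quantiles of `x` and boundary knots at the range of `x`
#' (`n_knots + 1` columns). Together with an intercept the basis
#' reproduces any linear function of `x` exactly.
#'
#' @param x numeric vector (non-degenerate).
#' @param n_knots number of interior knots (>= 1).
#' @param ref optional reference vector defining knot locations and
#'   boundaries (used to evaluate the basis for new data).
#' @return matrix with `n_knots + 1` columns.
#' @export
time_spline_basis <- function(x, n_knots = 3L, ref = x) {
  if (n_knots < 1L) stop("n_knots must be >= 1", call. = FALSE)
  if (diff(range(ref)) == 0) stop("cannot build a spline basis on constant x",
                                  call. = FALSE)
  probs <- seq_len(n_knots) / (n_knots + 1)
  knots <- unname(stats::quantile(ref, probs))
  b <- splines::ns(x, knots = knots, Boundary.knots = range(ref))
  colnames(b) <- paste0("s", seq_len(ncol(b)))
  unclass(b)[, , drop = FALSE]
}

#' Wald confidence interval
#'
#' `coef +/- z * se`, optionally exponentiated for reporting odds or
#' geometric mean ratios.
#'
#' @param coef,se point estimate and standard error (log scale for
#'   ratio effects).
#' @param level confidence level.
#' @param exponentiate return `exp()` of the bounds?
#' @return named vector `c(low, high)`.
#' @export
wald_ci <- function(coef, se, level = 0.95, exponentiate = FALSE) {
  if (any(se <= 0)) stop("se must be positive", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- c(low = coef - z * se, high = coef + z * se)
  if (exponentiate) out <- exp(out)
  out
}

new_sw_fit <- function(beta, vcov_beta, re_sd, loglik, converged, boundary,
                       n_used, method, y, fitted, family, weights,
                       effect_term = "intervention") {
  est <- unname(beta[effect_term])
  effect <- NULL
  if (effect_term %in% names(beta)) {
    se <- sqrt(vcov_beta[effect_term, effect_term])
    ci <- wald_ci(est, se, exponentiate = TRUE)
    effect <- list(scale = if (family == "binomial") "OR" else "GMR",
                   term = effect_term, log_estimate = est, se_log = se,
                   estimate = exp(est), ci_low = unname(ci["low"]),
                   ci_high = unname(ci["high"]))
  }
  structure(list(coefficients = beta, vcov = vcov_beta, re_sd = re_sd,
                 loglik = loglik, converged = converged, boundary = boundary,
                 n_used = n_used, method = method, family = family,
                 y = y, fitted = fitted, weights = weights, effect = effect),
            class = "sw_fit")
}

# ---- linear mixed model (random site intercept == compound symmetry) -------

#' Random-intercept linear mixed model by profiled REML
#'
#' Gaussian mixed model `y = X beta + u[cluster] + e` with a single random
#' intercept per cluster, the model form whose marginal covariance is
#' compound symmetry within cluster. The variance ratio is profiled out and
#' the (restricted) likelihood maximised on the log-ratio scale; weights
#' act as frequency-style precision weights on the residuals. When the
#' fitted between-cluster variance is zero the estimates coincide with
#' (weighted) ordinary least squares.
#'
#' @param X fixed-effects design matrix with named columns.
#' @param y numeric outcome (log hours for length-of-stay models).
#' @param cluster cluster (site) membership per row.
#' @param weights positive per-row weights, default 1.
#' @param reml use REML (default) or ML.
#' @return an object of class [`sw_fit`][print.sw_fit]; the intervention
#'   effect, when present, is reported as a geometric mean ratio.
#' @export
sw_lmm <- function(X, y, cluster, weights = NULL, reml = TRUE) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, length(cluster) == n)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  cl <- factor(cluster[keep]); w <- weights[keep]
  if (qr(X)$rank < ncol(X))
    stop("fixed-effects design matrix is rank deficient", call. = FALSE)
  p <- ncol(X)
  n_eff <- sum(w)
  cl_i <- split(seq_along(y), cl)

  # per-cluster sufficient statistics under V* = diag(1/w) + lambda * 11'
  suff <- lapply(cl_i, function(i) {
    Xi <- X[i, , drop = FALSE]; yi <- y[i]; wi <- w[i]
    list(XtWX = crossprod(Xi, Xi * wi), XtWy = crossprod(Xi, yi * wi),
         ytWy = sum(wi * yi^2), Xtw = crossprod(Xi, wi), ytw = sum(wi * yi),
         sw = sum(wi), logw = sum(log(wi)))
  })

  gls <- function(lambda) {
    A <- matrix(0, p, p); b <- numeric(p); q <- 0; ldet <- 0
    for (s in suff) {
      f <- lambda / (1 + lambda * s$sw)
      A <- A + s$XtWX - f * tcrossprod(s$Xtw)
      b <- b + s$XtWy - f * s$Xtw * s$ytw
      q <- q + s$ytWy - f * s$ytw^2
      ldet <- ldet - s$logw + log1p(lambda * s$sw)
    }
    beta <- solve(A, b)
    rss <- q - 2 * sum(beta * b) + sum(beta * (A %*% beta))
    list(A = A, beta = drop(beta), rss = max(rss, 1e-12), ldet = ldet)
  }

  crit <- function(loglambda) {
    g <- gls(exp(loglambda))
    df <- if (reml) n_eff - p else n_eff
    s2 <- g$rss / df
    val <- df * log(s2) + g$ldet + df
    if (reml) val <- val + determinant(g$A, logarithm = TRUE)$modulus - p * log(s2)
    as.numeric(val)
  }

  opt <- stats::optimize(crit, interval = c(-18, 12), tol = 1e-9)
  # accept the no-clustering boundary when it is criterion-equivalent
  if (crit(-18) <= opt$objective + 1e-4) opt <- list(minimum = -Inf, objective = crit(-18))
  lambda <- exp(opt$minimum)
  boundary <- !is.finite(opt$minimum) || lambda < 1e-7
  if (boundary) lambda <- 0
  g <- gls(lambda)
  df <- if (reml) n_eff - p else n_eff
  s2 <- g$rss / df
  vcov_beta <- solve(g$A) * s2
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  beta <- stats::setNames(g$beta, colnames(X))
  ll <- -0.5 * (df * log(2 * pi * s2) + g$ldet + g$rss / s2 +
                  if (reml) as.numeric(determinant(g$A / s2, logarithm = TRUE)$modulus) else 0)
  # BLUP-free fitted values: fixed part only
  fitted <- drop(X %*% g$beta)
  fit <- new_sw_fit(beta, vcov_beta, re_sd = c(site = sqrt(lambda * s2)),
                    loglik = ll, converged = TRUE, boundary = boundary,
                    n_used = length(y), method = if (reml) "LMM-REML" else "LMM-ML",
                    y = y, fitted = fitted, family = "gaussian", weights = w)
  fit$sigma <- sqrt(s2)
  fit
}

# ---- logistic mixed model ---------------------------------------------------

gh_rule <- function(k) {
  r <- pracma::gaussHermite(k)
  list(nodes = r$x, weights = r$w)
}

# vectorised scalar-mode search for all clusters at once; returns mode u
# and per-cluster aggregates at the mode. Rows must be sorted by cluster;
# `cl` holds integer codes 1..C and `ends` the block ends.
scalar_modes <- function(eta0, y, w, cl, ends, s2, u0) {
  u <- u0
  for (it in 1:100) {
    eta <- eta0 + u[cl]
    mu <- inv_logit(eta)
    g1 <- group_sums(w * (y - mu), ends) - u / s2
    J <- group_sums(w * mu * (1 - mu), ends)
    step <- g1 / (J + 1 / s2)
    step <- pmin(pmax(step, -4), 4)
    u <- u + step
    if (max(abs(step)) < 1e-9) break
  }
  eta <- eta0 + u[cl]
  mu <- inv_logit(eta)
  list(u = u, mu = mu,
       h = group_sums(w * (y * eta - log1pexp(eta)), ends),
       J = group_sums(w * mu * (1 - mu), ends))
}

# marginal log-likelihood (and, for the Laplace method, its analytic
# gradient) of the random-intercept logistic model at (beta, log sigma).
# Rows must be sorted by cluster code.
marglik_internal <- function(pars, X, y, w, cl, method, rule, grad = FALSE,
                             u_start = NULL, ends = NULL) {
  p <- ncol(X)
  beta <- pars[seq_len(p)]
  sigma <- exp(pars[p + 1])
  s2 <- sigma^2
  eta0 <- drop(X %*% beta)
  cl <- as.integer(cl)
  if (is.null(ends)) ends <- cumsum(tabulate(cl))
  C <- length(ends)
  if (is.null(u_start)) u_start <- numeric(C)
  m <- scalar_modes(eta0, y, w, cl, ends, s2, u_start)
  D <- m$J + 1 / s2
  if (method == "Laplace") {
    ll_c <- m$h - m$u^2 / (2 * s2) - 0.5 * log1p(s2 * m$J)
  } else {
    tau <- 1 / sqrt(D)
    g0 <- m$h - m$u^2 / (2 * s2)
    acc <- matrix(0, C, length(rule$nodes))
    for (j in seq_along(rule$nodes)) {
      uj <- m$u + sqrt(2) * tau * rule$nodes[j]
      etaj <- eta0 + uj[cl]
      gj <- group_sums(w * (y * etaj - log1pexp(etaj)), ends) -
        uj^2 / (2 * s2)
      acc[, j] <- log(rule$weights[j]) + gj + rule$nodes[j]^2 - g0
    }
    ll_c <- g0 + log(rowSums(exp(acc))) + 0.5 * log(2) + log(tau) -
      log(sigma) - 0.5 * log(2 * pi)
  }
  out <- list(loglik = sum(ll_c), ll_c = ll_c, u = m$u)
  if (grad) {
    if (method != "Laplace")
      stop("analytic gradient implemented for the Laplace method only")
    mu <- m$mu
    v <- w * mu * (1 - mu)
    vp <- v * (1 - 2 * mu)
    # per-cluster aggregates of covariate-weighted terms, via one pass of
    # column-wise cumulative sums at the block ends
    agg <- function(vec) {
      A <- apply(vec * X, 2, cumsum)[ends, , drop = FALSE]
      if (C > 1L) A - rbind(0, A[-C, , drop = FALSE]) else A
    }
    R <- agg(w * (y - mu))
    S <- agg(v)
    Tm <- agg(vp)
    Jp <- group_sums(vp, ends)
    dJ <- Tm - (Jp / D) * S
    g_beta <- colSums(R - 0.5 * dJ / D)
    g_theta <- sum(m$u^2 / s2 - m$J / D - Jp * m$u / (s2 * D^2))
    out$grad <- c(g_beta, g_theta)
  }
  out
}

#' Marginal log-likelihood of the random-intercept logistic model
#'
#' Evaluates, at fixed parameters, the marginal likelihood in which each
#' cluster's Bernoulli likelihood is integrated over a Gaussian random
#' intercept — by the Laplace approximation or by adaptive Gauss-Hermite
#' quadrature with `n_nodes` mode-centred nodes (Laplace is the one-node
#' case). Exposed so the quadrature can be checked against brute-force
#' integration.
#'
#' @inheritParams sw_lmm
#' @param beta fixed-effect coefficients.
#' @param sigma_u random-intercept SD.
#' @param method `"Laplace"` or `"AGQ"`.
#' @param n_nodes quadrature nodes for `"AGQ"`.
#' @return list with `loglik` (total) and `ll_c` (per cluster).
#' @export
glmm_marglik <- function(X, y, cluster, beta, sigma_u, weights = NULL,
                         method = c("AGQ", "Laplace"), n_nodes = 25L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  cl <- factor(cluster)
  if (is.null(weights)) weights <- rep(1, length(y))
  rule <- if (method == "AGQ") gh_rule(n_nodes) else NULL
  ord <- order(as.integer(cl))
  r <- marglik_internal(c(beta, log(max(sigma_u, 1e-12))), X[ord, , drop = FALSE],
                        y[ord], weights[ord], as.integer(cl)[ord], method, rule)
  list(loglik = r$loglik, ll_c = stats::setNames(r$ll_c, levels(cl)))
}

#' Brute-force marginal likelihood oracle for one cluster
#'
#' Computes the random-intercept marginal log-likelihood of a single small
#' cluster by adaptive numerical integration (`stats::integrate`) of the
#' Bernoulli likelihood against the Gaussian random-effect density. This is
#' the reference the quadrature code is validated against; it shares no
#' code with the quadrature path.
#'
#' @param X_c,y_c design matrix and binary outcome for the cluster rows.
#' @param beta fixed-effect coefficients.
#' @param sigma_u random-intercept SD (0 gives the plain Bernoulli
#'   log-likelihood).
#' @param weights per-row weights.
#' @return the cluster's marginal log-likelihood.
#' @export
cluster_marglik_oracle <- function(X_c, y_c, beta, sigma_u, weights = NULL) {
  X_c <- as.matrix(X_c)
  if (is.null(weights)) weights <- rep(1, length(y_c))
  eta0 <- drop(X_c %*% beta)
  h <- function(u) {
    vapply(u, function(ui) {
      eta <- eta0 + ui
      sum(weights * (y_c * eta - log1pexp(eta)))
    }, numeric(1))
  }
  if (sigma_u <= 0) return(h(0))
  # shift by the integrand's maximum on a coarse grid for numerical stability
  gr <- seq(-8 * sigma_u, 8 * sigma_u, length.out = 161)
  g <- h(gr) + stats::dnorm(gr, 0, sigma_u, log = TRUE)
  g0 <- max(g)
  f <- function(u) exp(h(u) + stats::dnorm(u, 0, sigma_u, log = TRUE) - g0)
  int <- stats::integrate(f, -Inf, Inf, rel.tol = 1e-12, abs.tol = 1e-13,
                          subdivisions = 500L)
  g0 + log(int$value)
}

#' Random-intercept(/slope) logistic mixed model
#'
#' Maximum-likelihood estimation of a logistic mixed model for a binary
#' endpoint with cluster (site) random effects. The marginal likelihood is
#' approximated by adaptive Gauss-Hermite quadrature for a scalar random
#' intercept, or by the Laplace approximation (the one-node case, also the
#' only method offered for two-dimensional random effects — random
#' intervention or random time slope). Optimisation is quasi-Newton (BFGS)
#' over the fixed effects and log-scale variance parameters, with restarts
#' from sigma in {0.1, 1} on failure; analytic gradients are used on the
#' Laplace path. Per-row weights multiply log-likelihood contributions
#' (frequency-style), so IPTW fits are supported directly. A between-
#' cluster variance estimated at the zero boundary is reported as 0 with
#' `boundary = TRUE` (and the fixed effects then coincide with plain
#' weighted logistic regression).
#'
#' @inheritParams sw_lmm
#' @param y binary outcome (0/1).
#' @param Z optional second random-effect column (e.g. the intervention
#'   indicator or scaled time) giving random structure `intercept + Z` with
#'   unstructured 2x2 covariance; requires `method = "Laplace"`.
#' @param method `"Laplace"` (default: the estimation switch used for all
#'   post-hoc safety models, for speed of convergence) or `"AGQ"`.
#' @param n_nodes adaptive Gauss-Hermite nodes when `method = "AGQ"`
#'   (default 25).
#' @param robust also compute a cluster-robust sandwich covariance
#'   (stored as `vcov_robust`; Wald CIs still use the model-based
#'   covariance unless `use_robust = TRUE`).
#' @param use_robust base the reported effect CI on the sandwich
#'   covariance.
#' @return an object of class [`sw_fit`][print.sw_fit]; the intervention
#'   effect, when present, is reported as an odds ratio.
#' @export
sw_glmm <- function(X, y, cluster, weights = NULL, Z = NULL,
                    method = c("Laplace", "AGQ"), n_nodes = 25L,
                    robust = FALSE, use_robust = FALSE) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, length(cluster) == n, all(y %in% 0:1))
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  if (qr(X)$rank < ncol(X)) {
    d <- qr(X)
    bad <- colnames(X)[d$pivot[-seq_len(d$rank)]]
    stop("fixed-effects design matrix is rank deficient; offending columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cl <- factor(cluster)
  if (!is.null(Z)) {
    # two-dimensional random effects are fitted by the Laplace method only
    return(sw_glmm_2d(X, y, cl, weights, Z))
  }
  p <- ncol(X)
  rule <- if (method == "AGQ") gh_rule(n_nodes) else NULL

  # sort rows by cluster once so per-cluster sums are contiguous-block sums
  ord <- order(as.integer(cl))
  Xs <- X[ord, , drop = FALSE]
  ys <- y[ord]
  ws <- weights[ord]
  cls <- as.integer(cl)[ord]
  ends <- cumsum(tabulate(cls, nbins = nlevels(cl)))

  start_glm <- suppressWarnings(
    stats::glm.fit(Xs, ys, weights = ws, family = stats::binomial()))
  cache <- new.env(parent = emptyenv())
  cache$u <- numeric(nlevels(cl))
  eval_at <- function(pars, grad, mth = method) {
    r <- marglik_internal(pars, Xs, ys, ws, cls, mth, rule, grad = grad,
                          u_start = cache$u, ends = ends)
    cache$u <- r$u
    r
  }
  fn_lap <- function(pars) -eval_at(pars, grad = FALSE, mth = "Laplace")$loglik
  gr_lap <- function(pars) -eval_at(pars, grad = TRUE, mth = "Laplace")$grad

  # box on log sigma: the lower bound is the zero-variance boundary (the
  # optimiser stops there instead of crawling towards -Inf)
  fit_laplace <- function(sigma0) {
    stats::optim(c(start_glm$coefficients, log(sigma0)), fn_lap, gr_lap,
                 method = "L-BFGS-B",
                 lower = c(rep(-Inf, p), log(1e-4)),
                 upper = c(rep(Inf, p), log(20)),
                 control = list(maxit = 300, factr = 1e7))
  }
  opt <- fit_laplace(0.1)
  if (opt$convergence != 0) {
    opt2 <- fit_laplace(1)
    if (opt2$value < opt$value) opt <- opt2
  }
  if (method == "AGQ" && exp(opt$par[p + 1]) >= 1e-3) {
    # polish the Laplace optimum under the quadrature objective
    fn <- function(pars) -eval_at(pars, grad = FALSE)$loglik
    gr <- function(pars) num_gradient(fn, pars)
    opt_q <- stats::optim(opt$par, fn, gr, method = "BFGS",
                          control = list(maxit = 200, reltol = 1e-12))
    opt_q$convergence <- min(opt_q$convergence, opt$convergence)
    opt <- opt_q
  }
  converged <- opt$convergence == 0
  sigma_hat <- exp(opt$par[p + 1])
  boundary <- sigma_hat < 1e-3

  if (boundary) {
    # sigma -> 0 limit: plain weighted logistic regression
    beta <- stats::setNames(start_glm$coefficients, colnames(X))
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    info <- crossprod(X, X * (weights * mu * (1 - mu)))
    vcov_beta <- solve(info)
    ll <- sum(weights * (y * eta - log1pexp(eta)))
    re_sd <- c(site = 0)
    fitted <- mu
    converged <- TRUE
  } else {
    beta <- stats::setNames(opt$par[seq_len(p)], colnames(X))
    H <- if (method == "Laplace")
      num_jacobian(function(q) -eval_at(q, grad = TRUE)$grad, opt$par)
    else
      stats::optimHess(opt$par, function(q) -eval_at(q, grad = FALSE)$loglik,
                       control = list(ndeps = rep(1e-4, p + 1)))
    H <- (H + t(H)) / 2
    vcov_full <- tryCatch(solve(H), error = function(e) {
      warning("information matrix singular; using pseudo-inverse")
      pseudo_solve(H)
    })
    vcov_beta <- vcov_full[seq_len(p), seq_len(p), drop = FALSE]
    ll <- -opt$value
    re_sd <- c(site = sigma_hat)
    r <- eval_at(opt$par, grad = FALSE)
    fitted <- stats::plogis(drop(X %*% beta) + r$u[as.integer(cl)])
    if (any(!is.finite(diag(vcov_beta))) || any(diag(vcov_beta) <= 0)) {
      # near-flat variance direction: fall back to the conditional
      # information at the random-effect modes
      vv <- weights * fitted * (1 - fitted)
      vcov_beta <- solve(crossprod(X, X * vv))
      converged <- FALSE
    }
  }
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))

  fit <- new_sw_fit(beta, vcov_beta, re_sd, ll, converged, boundary,
                    n_used = n, method = if (method == "AGQ")
                      paste0("AGQ(", n_nodes, ")") else "Laplace",
                    y = y, fitted = fitted, family = "binomial",
                    weights = weights)
  if (robust || use_robust) {
    Vr <- sandwich_vcov(Xs, ys, ws, cls, beta, re_sd[[1]], method, n_nodes,
                        vcov_beta)
    fit$vcov_robust <- Vr
    if (use_robust && "intervention" %in% names(beta)) {
      se <- sqrt(Vr["intervention", "intervention"])
      ci <- wald_ci(beta[["intervention"]], se, exponentiate = TRUE)
      fit$effect$se_log <- se
      fit$effect$ci_low <- unname(ci["low"])
      fit$effect$ci_high <- unname(ci["high"])
    }
  }
  fit
}

# cluster-robust sandwich: B^-1 M B^-1 with M the outer product of
# per-cluster score contributions (beta block only), scores by central
# differences of the per-cluster marginal log-likelihoods
sandwich_vcov <- function(X, y, w, cl, beta, sigma, method, n_nodes, bread) {
  p <- length(beta)
  rule <- if (method == "AGQ") gh_rule(n_nodes) else NULL
  ll_c <- function(b) marglik_internal(c(b, log(max(sigma, 1e-8))), X, y, w, cl,
                                       method, rule)$ll_c
  C <- length(unique(cl))
  Sc <- matrix(0, C, p)
  h <- 1e-5 * (1 + abs(beta))
  for (k in seq_len(p)) {
    bp <- beta; bp[k] <- bp[k] + h[k]
    bm <- beta; bm[k] <- bm[k] - h[k]
    Sc[, k] <- (ll_c(bp) - ll_c(bm)) / (2 * h[k])
  }
  M <- crossprod(Sc) * C / max(C - 1, 1)
  V <- bread %*% M %*% bread
  dimnames(V) <- dimnames(bread)
  V
}

# ---- two-dimensional random effects (random intervention / time slope) -----

sw_glmm_2d <- function(X, y, cl, w, z2) {
  p <- ncol(X)
  C <- nlevels(cl)
  rows <- split(seq_along(y), cl)

  nll <- function(pars) {
    beta <- pars[seq_len(p)]
    L <- matrix(c(exp(pars[p + 1]), pars[p + 3], 0, exp(pars[p + 2])), 2, 2)
    Sigma <- tcrossprod(L)
    Q <- tryCatch(solve(Sigma), error = function(e) NULL)
    if (is.null(Q)) return(1e10)
    eta0 <- drop(X %*% beta)
    ldSigma <- 2 * (pars[p + 1] + pars[p + 2])
    total <- 0
    for (ci in seq_len(C)) {
      i <- rows[[ci]]
      Zi <- cbind(1, z2[i]); yi <- y[i]; wi <- w[i]; e0 <- eta0[i]
      u <- c(0, 0)
      for (it in 1:100) {
        eta <- e0 + Zi %*% u
        mu <- stats::plogis(drop(eta))
        g <- drop(crossprod(Zi, wi * (yi - mu))) - Q %*% u
        v <- wi * mu * (1 - mu)
        A <- crossprod(Zi, Zi * v) + Q
        step <- solve(A, g)
        nrm <- sqrt(sum(step^2))
        if (nrm > 4) step <- step * 4 / nrm
        u <- u + drop(step)
        if (max(abs(step)) < 1e-10) break
      }
      eta <- drop(e0 + Zi %*% u)
      mu <- stats::plogis(eta)
      v <- wi * mu * (1 - mu)
      A <- crossprod(Zi, Zi * v) + Q
      g_u <- sum(wi * (yi * eta - log1pexp(eta))) -
        0.5 * drop(crossprod(u, Q %*% u))
      total <- total + g_u - 0.5 * ldSigma -
        0.5 * as.numeric(determinant(A, logarithm = TRUE)$modulus)
    }
    -total
  }

  start_glm <- suppressWarnings(
    stats::glm.fit(X, y, weights = w, family = stats::binomial()))
  start <- c(start_glm$coefficients, log(0.1), log(0.1), 0)
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  if (opt$convergence != 0) {
    opt2 <- stats::optim(c(start_glm$coefficients, log(1), log(1), 0), nll,
                         method = "BFGS",
                         control = list(maxit = 500, reltol = 1e-10))
    if (opt2$value < opt$value) opt <- opt2
  }
  beta <- stats::setNames(opt$par[seq_len(p)], colnames(X))
  L <- matrix(c(exp(opt$par[p + 1]), opt$par[p + 3], 0, exp(opt$par[p + 2])), 2, 2)
  Sigma <- tcrossprod(L)
  re_sd <- c(site = sqrt(Sigma[1, 1]), slope = sqrt(Sigma[2, 2]))
  boundary <- any(re_sd < 1e-3)
  H <- tryCatch(stats::optimHess(opt$par, nll), error = function(e) NULL)
  vcov_beta <- NULL
  if (!is.null(H)) {
    H <- (H + t(H)) / 2
    vcov_full <- tryCatch(solve(H), error = function(e) pseudo_solve(H))
    vcov_beta <- vcov_full[seq_len(p), seq_len(p), drop = FALSE]
  }
  if (is.null(vcov_beta) || any(!is.finite(diag(vcov_beta))) ||
      any(diag(vcov_beta) <= 0)) {
    # fall back to the conditional information at the modes
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    vcov_beta <- solve(crossprod(X, X * (w * mu * (1 - mu))))
  }
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  mu_hat <- stats::plogis(drop(X %*% beta))
  new_sw_fit(beta, vcov_beta, re_sd, -opt$value,
             converged = opt$convergence == 0, boundary = boundary,
             n_used = length(y), method = "Laplace-2D", y = y,
             fitted = mu_hat, family = "binomial", weights = w)
}

# ---- small numerical helpers ------------------------------------------------

num_gradient <- function(f, x, h = 1e-6 * (1 + abs(x))) {
  g <- numeric(length(x))
  for (k in seq_along(x)) {
    xp <- x; xp[k] <- xp[k] + h[k]
    xm <- x; xm[k] <- xm[k] - h[k]
    g[k] <- (f(xp) - f(xm)) / (2 * h[k])
  }
  g
}

num_jacobian <- function(f, x, h = 1e-5 * (1 + abs(x))) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (k in seq_along(x)) {
    xp <- x; xp[k] <- xp[k] + h[k]
    xm <- x; xm[k] <- xm[k] - h[k]
    J[, k] <- (f(xp) - f(xm)) / (2 * h[k])
  }
  J
}

pseudo_solve <- function(H, tol = 1e-10) {
  s <- svd(H)
  d <- ifelse(s$d > tol * max(s$d), 1 / s$d, 0)
  s$v %*% (d * t(s$u))
}
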