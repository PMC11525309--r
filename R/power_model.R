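#' Specify a focal effect for analytic power
#'
#' An effect specification carries the population value of the focal parameter
#' and the per-sqrt(n) scale of its standard error. For an M-estimator with
#' sandwich asymptotic covariance (1/n) H^-1 I H^-1, the standard error of the
#' focal estimate at sample size n is `avar_factor / sqrt(n)`, where
#' `avar_factor` is the square root of the focal diagonal element of
#' H^-1 I H^-1. Together with the test level and sidedness this determines the
#' asymptotic power curve of the z-test.
#'
#' @param theta0 population value of the focal parameter (model units).
#' @param avar_factor per-sqrt(n) standard-error scale (must be `> 0`).
#' @param sided `"one_sided"` or `"two_sided"`.
#' @param alpha test level in (0, 1).
#'
#' @return An object of class `mspe_effect`.
#' @examples
#' eff <- effect_spec(theta0 = 0.2, avar_factor = 2)
#' analytic_power(eff, n = 400)
#' @export
effect_spec <- function(theta0, avar_factor,
                        sided = c("one_sided", "two_sided"), alpha = 0.05) {
  sided <- match.arg(sided)
  if (!is.finite(avar_factor) || avar_factor <= 0) {
    mspe_abort("avar_factor must be a positive finite number", "mspe_effect_error")
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    mspe_abort("alpha must lie in (0, 1)", "mspe_effect_error")
  }
  structure(list(theta0 = theta0, avar_factor = avar_factor,
                 sided = sided, alpha = alpha),
            class = "mspe_effect")
}

#' Asymptotic power of the z-test
#'
#' Approximates the power of the one- or two-sided z-test for a focal
#' parameter, using the asymptotic normality of M-estimates. With
#' noncentrality `mu = |theta0| / avar_factor * sqrt(n)`, the one-sided power
#' is `Phi(-q_{1-alpha} + mu)`; the two-sided power is
#' `Phi(-q_{1-alpha/2} + mu) + Phi(-q_{1-alpha/2} - mu)`.
#'
#' @param effect an [effect_spec()].
#' @param n sample size(s), each `>= 1`.
#'
#' @return Numeric vector of power values in (0, 1).
#' @export
analytic_power <- function(effect, n) {
  stopifnot(inherits(effect, "mspe_effect"))
  if (any(n < 1)) mspe_abort("n must be >= 1", "mspe_effect_error")
  mu <- abs(effect$theta0) / effect$avar_factor * sqrt(n)
  if (effect$sided == "one_sided") {
    stats::pnorm(-stats::qnorm(1 - effect$alpha) + mu)
  } else {
    q <- stats::qnorm(1 - effect$alpha / 2)
    stats::pnorm(-q + mu) + stats::pnorm(-q - mu)
  }
}

## ---- binary power-curve regressions -------------------------------------

power_model_methods <- c("probit_sqrt", "wald_sqrt", "probit_n",
                         "logit_sqrt", "logit_n", "naive")

#' @keywords internal
#' @noRd
predictor_transform <- function(method) {
  if (grepl("_sqrt$", method)) sqrt else identity
}

#' @keywords internal
#' @noRd
link_functions <- function(link) {
  if (link == "probit") {
    list(linkinv = stats::pnorm, linkfun = stats::qnorm)
  } else {
    list(linkinv = stats::plogis, linkfun = stats::qlogis)
  }
}

# Log-likelihood, gradient and (observed-information) Hessian weights for a
# binary regression with probit or logit link. For the probit link the
# per-case curvature is m(q)(q + m(q)) with q = (2y - 1) * eta and
# m the inverse Mills ratio, evaluated on the log scale for stability.
#' @keywords internal
#' @noRd
binreg_derivs <- function(y, eta, link) {
  if (link == "logit") {
    p <- stats::plogis(eta)
    list(ll = sum(ifelse(y == 1, stats::plogis(eta, log.p = TRUE),
                         stats::plogis(-eta, log.p = TRUE))),
         u = y - p, w = p * (1 - p))
  } else {
    q <- ifelse(y == 1, eta, -eta)
    m <- exp(stats::dnorm(q, log = TRUE) - stats::pnorm(q, log.p = TRUE))
    list(ll = sum(stats::pnorm(q, log.p = TRUE)),
         u = ifelse(y == 1, m, -m), w = m * (q + m))
  }
}

#' @keywords internal
#' @noRd
detect_separation <- function(y, g) {
  if (all(y == 0L)) {
    mspe_abort(paste("all significance decisions are 0: the power curve is",
                     "not identified; widen the n range toward larger n"),
               "mspe_separation_error")
  }
  if (all(y == 1L)) {
    mspe_abort(paste("all significance decisions are 1: the power curve is",
                     "not identified; widen the n range toward smaller n"),
               "mspe_separation_error")
  }
  if (max(g[y == 0L]) < min(g[y == 1L]) || max(g[y == 1L]) < min(g[y == 0L])) {
    mspe_abort(paste("complete separation: outcomes are perfectly ordered by",
                     "the predictor; widen the n range so both outcomes occur",
                     "throughout"),
               "mspe_separation_error")
  }
  invisible(TRUE)
}

#' @keywords internal
#' @noRd
binreg_start <- function(y, g, link) {
  lk <- link_functions(link)
  br <- unique(stats::quantile(g, c(0, .25, .5, .75, 1)))
  if (length(br) < 3) return(c(lk$linkfun(max(min(mean(y), .99), .01)), 0))
  bins <- cut(g, breaks = br, include.lowest = TRUE)
  p <- tapply(y, bins, mean)
  gm <- tapply(g, bins, mean)
  eps <- 1 / (2 * length(y))
  z <- lk$linkfun(pmin(pmax(p, eps), 1 - eps))
  cf <- stats::coef(stats::lm(z ~ gm))
  if (!all(is.finite(cf))) cf <- c(lk$linkfun(mean(y)), 0)
  unname(cf)
}

#' Fit a parametric power-curve model to significance decisions
#'
#' Fits a binary regression for the probability of a significant z-test as a
#' function of sample size: mean `F(beta0 + beta1 * g(n))` with `F` the
#' standard-normal or logistic distribution function and `g(n) = sqrt(n)` or
#' `n`. For decisions produced by a one-sided z-test on an asymptotically
#' normal estimate, the probit regression on `sqrt(n)` is the correctly
#' specified model, with asymptotic coefficients
#' `(-q_{1-alpha}, |theta0|/avar_factor)`; the other links/predictors are
#' provided as comparison methods. Maximisation is by Newton-Raphson with
#' step-halving on the log-likelihood (gradient tolerance 1e-8, at most 100
#' iterations); the coefficient covariance is the inverse observed information
#' at the optimum. Non-converged records are dropped before fitting and the
#' drop count is reported.
#'
#' @param records a significance-record table (see [significance_records()]).
#' @param method one of `"probit_sqrt"`, `"probit_n"`, `"logit_sqrt"`,
#'   `"logit_n"`.
#' @param alpha the test level that produced the decisions (stored for
#'   diagnostics: asymptotically `beta0 = -q_{1-alpha}` for `probit_sqrt`).
#'
#' @return An object of class `mspe_power_fit` with elements `method`,
#'   `alpha`, `beta0`, `beta1`, `vcov`, `loglik`, `n_records`,
#'   `dropped_nonconverged`, `converged`, `iterations`.
#' @seealso [fit_wald_power_model()] for the two-sided variant,
#'   [fit_naive()] for the interpolation baseline.
#' @export
fit_power_model <- function(records,
                            method = c("probit_sqrt", "probit_n",
                                       "logit_sqrt", "logit_n"),
                            alpha = 0.05) {
  method <- match.arg(method)
  cr <- converged_records(records)
  rec <- cr$records
  if (length(unique(rec$n)) < 2) {
    mspe_abort("need at least 2 distinct sample sizes among converged records",
               "mspe_parse_error")
  }
  y <- rec$significant
  g <- predictor_transform(method)(rec$n)
  detect_separation(y, g)
  link <- if (grepl("^probit", method)) "probit" else "logit"

  X <- cbind(1, g)
  beta <- binreg_start(y, g, link)
  conv <- FALSE
  iter <- 0L
  ll_old <- binreg_derivs(y, X %*% beta, link)$ll
  for (iter in seq_len(100L)) {
    d <- binreg_derivs(y, drop(X %*% beta), link)
    grad <- drop(crossprod(X, d$u))
    if (sqrt(sum(grad^2)) < 1e-8) { conv <- TRUE; break }
    H <- crossprod(X * d$w, X)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    t_ <- 1
    repeat {
      beta_new <- beta + t_ * step
      ll_new <- binreg_derivs(y, drop(X %*% beta_new), link)$ll
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
      t_ <- t_ / 2
      if (t_ < 1e-10) break
    }
    beta <- beta + t_ * step
    ll_old <- binreg_derivs(y, drop(X %*% beta), link)$ll
  }
  d <- binreg_derivs(y, drop(X %*% beta), link)
  H <- crossprod(X * d$w, X)
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 2, 2))
  if (!conv && sqrt(sum(drop(crossprod(X, d$u))^2)) < 1e-8) conv <- TRUE

  structure(list(method = method, alpha = alpha,
                 beta0 = unname(beta[1]), beta1 = unname(beta[2]),
                 vcov = unname(vc), naive_table = NULL,
                 loglik = d$ll, n_records = nrow(rec),
                 dropped_nonconverged = cr$dropped,
                 converged = conv, iterations = iter),
            class = "mspe_power_fit")
}

#' Fit the two-sided (Wald) power-curve model
#'
#' For a two-sided z-test the significance probability is a two-term mean
#' function `P(S = 1 | n) = Phi(beta0 + beta1*sqrt(n)) +
#' Phi(beta0 - beta1*sqrt(n))` (asymptotically `beta0 = -q_{1-alpha/2}`,
#' `beta1 = |theta0|/avar_factor`). No standard GLM link matches this mean, so
#' the likelihood is maximised directly by box-constrained quasi-Newton
#' (`beta1 >= 0`), seeded from the one-sided probit fit; the coefficient
#' covariance is the inverse observed information from a numerical Hessian.
#'
#' @inheritParams fit_power_model
#' @param alpha the two-sided test level that produced the decisions.
#' @return An `mspe_power_fit` with `method = "wald_sqrt"`; a boundary
#'   solution `beta1 = 0` is flagged via `boundary = TRUE`.
#' @export
fit_wald_power_model <- function(records, alpha = 0.05) {
  cr <- converged_records(records)
  rec <- cr$records
  if (length(unique(rec$n)) < 2) {
    mspe_abort("need at least 2 distinct sample sizes among converged records",
               "mspe_parse_error")
  }
  y <- rec$significant
  sq <- sqrt(rec$n)
  detect_separation(y, sq)

  start <- tryCatch({
    pf <- fit_power_model(rec, "probit_sqrt", alpha = alpha)
    c(pf$beta0, max(pf$beta1, 1e-4))
  }, error = function(e) c(stats::qnorm(alpha / 2), 1e-3))

  negll <- function(b) {
    p <- stats::pnorm(b[1] + b[2] * sq) + stats::pnorm(b[1] - b[2] * sq)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(ifelse(y == 1, log(p), log1p(-p)))
  }
  opt <- stats::optim(start, negll, method = "L-BFGS-B",
                      lower = c(-Inf, 0),
                      control = list(maxit = 500, factr = 1e4))
  beta <- opt$par
  boundary <- beta[2] <= 1e-10
  vc <- if (boundary) {
    matrix(NA_real_, 2, 2)
  } else {
    H <- stats::optimHess(beta, negll)
    tryCatch(solve(H), error = function(e) matrix(NA_real_, 2, 2))
  }
  structure(list(method = "wald_sqrt", alpha = alpha,
                 beta0 = unname(beta[1]), beta1 = unname(beta[2]),
                 vcov = unname(vc), naive_table = NULL,
                 loglik = -opt$value, n_records = nrow(rec),
                 dropped_nonconverged = cr$dropped,
                 converged = opt$convergence == 0, boundary = boundary,
                 iterations = opt$counts[["function"]]),
            class = "mspe_power_fit")
}

#' Fit the naive four-point interpolation baseline
#'
#' The naive approach estimates power pointwise at exactly four sample sizes
#' (relative frequency of significance among converged replications) and joins
#' the estimates by straight lines. For each grid point a normal-approximation
#' confidence interval `p_hat +/- z_{1-alpha_rho/2} * sqrt(p_hat(1-p_hat)/R_j)`
#' is computed (clipped to \[0, 1\]); the lower-bound curve interpolates the
#' four lower bounds. No extrapolation outside the grid is defined.
#'
#' @inheritParams fit_power_model
#' @param alpha_rho error level of the per-point confidence intervals.
#' @param alpha the test level that produced the decisions.
#' @return An `mspe_power_fit` with `method = "naive"` and a `naive_table`
#'   data frame with columns `n`, `R_j`, `p_hat`, `lb`, `ub`.
#' @export
fit_naive <- function(records, alpha_rho = 0.05, alpha = 0.05) {
  cr <- converged_records(records)
  rec <- cr$records
  ns <- sort(unique(rec$n))
  if (length(ns) != 4) {
    mspe_abort(sprintf(
      "naive method needs records on exactly 4 distinct sample sizes (got %d)",
      length(ns)), "mspe_grid_error")
  }
  z <- stats::qnorm(1 - alpha_rho / 2)
  tab <- do.call(rbind, lapply(ns, function(nj) {
    s <- rec$significant[rec$n == nj]
    p <- mean(s)
    half <- z * sqrt(p * (1 - p) / length(s))
    data.frame(n = nj, R_j = length(s), p_hat = p,
               lb = max(0, p - half), ub = min(1, p + half))
  }))
  structure(list(method = "naive", alpha = alpha, alpha_rho = alpha_rho,
                 beta0 = NULL, beta1 = NULL, vcov = NULL,
                 naive_table = tab, loglik = NA_real_,
                 n_records = nrow(rec), dropped_nonconverged = cr$dropped,
                 converged = TRUE, iterations = 0L),
            class = "mspe_power_fit")
}

#' @export
print.mspe_power_fit <- function(x, ...) {
  cat("Power-curve model fit (", x$method, ")\n", sep = "")
  if (x$method == "naive") {
    print(x$naive_table, row.names = FALSE)
  } else {
    se <- sqrt(diag(x$vcov))
    cat(sprintf("  beta0 = %.4f (SE %.4f)   beta1 = %.4f (SE %.4f)\n",
                x$beta0, se[1], x$beta1, se[2]))
    if (x$method %in% c("probit_sqrt", "wald_sqrt")) {
      q <- if (x$method == "wald_sqrt") {
        -stats::qnorm(1 - x$alpha / 2)
      } else {
        -stats::qnorm(1 - x$alpha)
      }
      cat(sprintf("  diagnostic: beta0 - (-q) = %.4f (asymptotically 0)\n",
                  x$beta0 - q))
    }
  }
  cat(sprintf("  records used: %d (dropped non-converged: %d), converged: %s\n",
              x$n_records, x$dropped_nonconverged, x$converged))
  invisible(x)
}

## ---- prediction with confidence bands -----------------------------------

#' @keywords internal
#' @noRd
naive_interp <- function(tab, col, n) {
  if (any(n < min(tab$n)) || any(n > max(tab$n))) {
    mspe_abort(sprintf(
      "naive method cannot extrapolate outside its grid [%d, %d]",
      min(tab$n), max(tab$n)), "mspe_extrapolation_error")
  }
  stats::approx(tab$n, tab[[col]], xout = n)$y
}

#' Predict power (with a confidence band) from a fitted power-curve model
#'
#' For the probit/logit regressions the `1 - alpha_rho` band is computed on
#' the linear-predictor scale (`eta_hat +/- z * se(eta_hat)` with
#' `var(eta_hat) = x' V x`) and mapped through the monotone response function,
#' which keeps the band inside \[0, 1\] and preserves coverage. For the
#' two-sided Wald model the band is a delta-method interval on the probability
#' scale, clipped to \[0, 1\]. For the naive baseline the per-grid-point
#' intervals are linearly interpolated; requests outside the grid raise an
#' extrapolation error.
#'
#' @param fit an `mspe_power_fit`.
#' @param n sample size(s) at which to predict.
#' @param alpha_rho band error level (the band has level `1 - alpha_rho`).
#'
#' @return A `data.frame` of class `mspe_power_prediction` with columns `n`,
#'   `rho_hat`, `lb`, `ub`, `alpha_rho`.
#' @export
predict_power <- function(fit, n, alpha_rho = 0.05) {
  stopifnot(inherits(fit, "mspe_power_fit"))
  if (any(n < 1)) mspe_abort("n must be >= 1", "mspe_parse_error")
  z <- stats::qnorm(1 - alpha_rho / 2)

  if (fit$method == "naive") {
    out <- data.frame(n = n,
                      rho_hat = naive_interp(fit$naive_table, "p_hat", n),
                      lb = naive_interp(fit$naive_table, "lb", n),
                      ub = naive_interp(fit$naive_table, "ub", n))
  } else if (fit$method == "wald_sqrt") {
    if (!isTRUE(fit$converged)) {
      mspe_abort("cannot predict from a non-converged fit", "mspe_fit_error")
    }
    sq <- sqrt(n)
    a <- fit$beta0 + fit$beta1 * sq
    b <- fit$beta0 - fit$beta1 * sq
    p <- stats::pnorm(a) + stats::pnorm(b)
    se <- vapply(seq_along(n), function(i) {
      gr <- c(stats::dnorm(a[i]) + stats::dnorm(b[i]),
              sq[i] * (stats::dnorm(a[i]) - stats::dnorm(b[i])))
      sqrt(max(0, drop(gr %*% fit$vcov %*% gr)))
    }, numeric(1))
    out <- data.frame(n = n, rho_hat = p,
                      lb = pmax(0, p - z * se), ub = pmin(1, p + z * se))
  } else {
    if (!isTRUE(fit$converged)) {
      mspe_abort("cannot predict from a non-converged fit", "mspe_fit_error")
    }
    linkinv <- link_functions(
      if (grepl("^probit", fit$method)) "probit" else "logit")$linkinv
    g <- predictor_transform(fit$method)(n)
    eta <- fit$beta0 + fit$beta1 * g
    se_eta <- vapply(g, function(gi) {
      x <- c(1, gi)
      sqrt(max(0, drop(x %*% fit$vcov %*% x)))
    }, numeric(1))
    out <- data.frame(n = n, rho_hat = linkinv(eta),
                      lb = linkinv(eta - z * se_eta),
                      ub = linkinv(eta + z * se_eta))
  }
  out$alpha_rho <- alpha_rho
  class(out) <- c("mspe_power_prediction", class(out))
  out
}

## ---- inversion for required sample size ---------------------------------

#' @keywords internal
#' @noRd
check_rho <- function(rho, alpha) {
  if (rho > 0.99) {
    mspe_abort("target power rates above .99 are not evaluated (rho <= .99)",
               "mspe_cap_error")
  }
  if (rho <= alpha) {
    mspe_abort("target power must exceed the test level alpha", "mspe_cap_error")
  }
  invisible(TRUE)
}

# ceiling with a tiny float guard so that exact-integer inversions do not get
# bumped to the next integer by representation noise
#' @keywords internal
#' @noRd
ceil_guard <- function(x) as.integer(ceiling(x - 1e-9))

#' Required sample size for a target power
#'
#' Inverts a fitted power-curve model (or an analytic effect specification)
#' for the smallest sample size whose predicted power reaches the target
#' `rho`, rounding up to the next integer. For `probit_sqrt`/`logit_sqrt`
#' the inversion is `N = ceil(((F^-1(rho) - beta0)/beta1)^2)`; for
#' `probit_n`/`logit_n` it is linear in `n`; the two-sided Wald model and a
#' two-sided effect specification are inverted by monotone bisection of the
#' two-term mean function; the naive baseline takes the first upward crossing
#' of its interpolating polyline. Targets are capped at `rho <= .99`.
#'
#' @param fit_or_effect an `mspe_power_fit` or an [effect_spec()].
#' @param rho target power, in `(alpha, .99]`.
#'
#' @return Required sample size as a positive integer.
#' @examples
#' required_n(effect_spec(theta0 = .5, avar_factor = 1), rho = .80)
#' @export
required_n <- function(fit_or_effect, rho) {
  if (inherits(fit_or_effect, "mspe_effect")) {
    eff <- fit_or_effect
    check_rho(rho, eff$alpha)
    if (eff$sided == "one_sided") {
      beta0 <- -stats::qnorm(1 - eff$alpha)
      beta1 <- abs(eff$theta0) / eff$avar_factor
      if (beta1 <= 0) {
        mspe_abort("null effect: required sample size undefined",
                   "mspe_inversion_error")
      }
      x <- (stats::qnorm(rho) - beta0) / beta1
      return(if (x <= 1) 1L else ceil_guard(x^2))
    }
    if (abs(eff$theta0) <= 0) {
      mspe_abort("null effect: required sample size undefined",
                 "mspe_inversion_error")
    }
    return(bisect_smallest_n(function(n) analytic_power(eff, n), rho))
  }

  fit <- fit_or_effect
  stopifnot(inherits(fit, "mspe_power_fit"))
  check_rho(rho, fit$alpha)

  if (fit$method == "naive") {
    return(polyline_first_crossing(fit$naive_table$n, fit$naive_table$p_hat, rho))
  }
  if (!isTRUE(fit$converged)) {
    mspe_abort("cannot invert a non-converged fit", "mspe_fit_error")
  }
  if (fit$beta1 <= 0) {
    mspe_abort("beta1 <= 0: fitted power curve is not increasing in n",
               "mspe_inversion_error")
  }
  if (fit$method == "wald_sqrt") {
    return(bisect_smallest_n(function(n) {
      stats::pnorm(fit$beta0 + fit$beta1 * sqrt(n)) +
        stats::pnorm(fit$beta0 - fit$beta1 * sqrt(n))
    }, rho))
  }
  linkfun <- link_functions(
    if (grepl("^probit", fit$method)) "probit" else "logit")$linkfun
  x <- (linkfun(rho) - fit$beta0) / fit$beta1
  if (grepl("_sqrt$", fit$method)) {
    if (x <= 1) 1L else ceil_guard(x^2)  # already attained at n = 1
  } else {
    ceil_guard(max(x, 1))
  }
}

# smallest integer n in [1, 1e7] with f(n) >= rho, for f monotone increasing;
# continuous bisection to power-scale tolerance, then ceiling
#' @keywords internal
#' @noRd
bisect_smallest_n <- function(f, rho, n_max = 1e7) {
  if (f(1) >= rho) return(1L)
  if (f(n_max) < rho) {
    mspe_abort(sprintf("power does not reach %.3f within n <= %g", rho, n_max),
               "mspe_not_achievable_error")
  }
  lo <- 1; hi <- n_max
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (f(mid) >= rho) hi <- mid else lo <- mid
    if (hi - lo < 1e-6 || abs(f(hi) - rho) < 1e-12) break
  }
  ceil_guard(hi)
}

# first upward crossing of the piecewise-linear interpolant of (xs, ys)
#' @keywords internal
#' @noRd
polyline_first_crossing <- function(xs, ys, rho) {
  ord <- order(xs)
  xs <- xs[ord]; ys <- ys[ord]
  if (ys[1] >= rho) return(as.integer(xs[1]))
  for (j in seq_len(length(xs) - 1)) {
    if (ys[j] < rho && ys[j + 1] >= rho) {
      x <- xs[j] + (rho - ys[j]) / (ys[j + 1] - ys[j]) * (xs[j + 1] - xs[j])
      return(ceil_guard(x))
    }
  }
  mspe_abort(sprintf("interpolated power never reaches %.3f within the grid",
                     rho), "mspe_not_achievable_error")
}

#' Lower-bound required sample size from the confidence band
#'
#' Finds the smallest sample size whose `1 - alpha_rho` confidence-band lower
#' bound for predicted power reaches the target `rho` (bisection on n over
#' \[1, 1e7\], tolerance 1e-6 on the power scale, then ceiling). Because the
#' band lower bound sits below the point prediction, this lower-bound sample
#' size `N_lb` exceeds the point estimate `N_alpha`, and it is calibrated so
#' that `P(N_lb < true N) ~ alpha_rho / 2`. `rho_hat_lb` reports the point
#' prediction at the crossing, i.e. the power level whose band lower bound
#' equals `rho`. For the naive baseline the lower-bound polyline is
#' interpolated and its first crossing taken.
#'
#' @param fit an `mspe_power_fit`.
#' @param rho target power, in `(alpha, .99]`.
#' @param alpha_rho band error level.
#'
#' @return An object of class `mspe_samplesize`: a list with `rho`,
#'   `N_alpha`, `N_lb`, `rho_hat_lb`, `method`, `alpha_rho`.
#' @export
required_n_lb <- function(fit, rho, alpha_rho = 0.05) {
  stopifnot(inherits(fit, "mspe_power_fit"))
  check_rho(rho, fit$alpha)
  N_alpha <- required_n(fit, rho)

  if (fit$method == "naive") {
    tab <- fit$naive_table
    N_lb <- polyline_first_crossing(tab$n, tab$lb, rho)
    rho_hat_lb <- naive_interp(tab, "p_hat", min(max(N_lb, min(tab$n)),
                                                 max(tab$n)))
  } else {
    lbf <- function(n) predict_power(fit, n, alpha_rho)$lb
    if (lbf(1) >= rho) {
      n_star <- 1
    } else {
      if (lbf(1e7) < rho) {
        mspe_abort(sprintf(
          "band lower bound does not reach %.3f within n <= 1e7", rho),
          "mspe_not_achievable_error")
      }
      lo <- 1; hi <- 1e7
      for (i in 1:80) {
        mid <- (lo + hi) / 2
        if (lbf(mid) >= rho) hi <- mid else lo <- mid
        if (hi - lo < 1e-6 || abs(lbf(hi) - rho) < 1e-12) break
      }
      n_star <- hi
    }
    N_lb <- ceil_guard(n_star)
    rho_hat_lb <- predict_power(fit, n_star, alpha_rho)$rho_hat
  }
  N_lb <- max(N_lb, N_alpha)
  structure(list(rho = rho, N_alpha = N_alpha, N_lb = N_lb,
                 rho_hat_lb = rho_hat_lb, method = fit$method,
                 alpha_rho = alpha_rho),
            class = "mspe_samplesize")
}

#' @export
print.mspe_samplesize <- function(x, ...) {
  cat(sprintf(
    "Required sample size (%s): N = %d for power %.3f; lower-bound N = %d\n",
    x$method, x$N_alpha, x$rho, x$N_lb))
  cat(sprintf("  band level 1 - %.3f; power level at crossing: %.4f\n",
              x$alpha_rho, x$rho_hat_lb))
  invisible(x)
}
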