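# Normal-theory ML fitting of a covariance-structure model, with analytic
# gradient of the discrepancy function and sandwich (robust) standard errors.

# F_ML(theta) = log|Sigma| + tr(S Sigma^-1) - log|S| - p, plus its gradient.
# Gradient uses E = Sigma^-1 - Sigma^-1 S Sigma^-1 and closed-form dSigma:
# loadings 2*(E M)[i,k]; paths 2*(LG' E M)[i,j]; psi W (diag) / 2W (offdiag)
# with W = LG' E LG; theta diag E[i,i].
#' @keywords internal
#' @noRd
fml_objective <- function(theta_vec, spec, S, logdetS, want_grad = TRUE) {
  mats <- spec_matrices_at(spec, theta_vec)
  p <- nrow(mats$lambda); m <- ncol(mats$lambda)
  G <- tryCatch(solve(diag(m) - mats$beta), error = function(e) NULL)
  if (is.null(G)) return(list(value = NA_real_))
  LG <- mats$lambda %*% G
  Sigma <- LG %*% mats$psi %*% t(LG) + mats$theta
  Sigma <- (Sigma + t(Sigma)) / 2
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(list(value = NA_real_))
  Sinv <- chol2inv(ch)
  logdet <- 2 * sum(log(diag(ch)))
  value <- logdet + sum(Sinv * S) - logdetS - p
  if (!want_grad) return(list(value = value, Sigma = Sigma, Sinv = Sinv))

  E <- Sinv - Sinv %*% S %*% Sinv
  A <- G %*% mats$psi %*% t(G)
  M <- mats$lambda %*% A
  EM <- E %*% M
  tLG_EM <- crossprod(LG, EM)
  W <- crossprod(LG, E %*% LG)
  tab <- spec$param_table
  grad <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    r <- tab$row[i]; cc <- tab$col[i]
    grad[i] <- switch(tab$matrix[i],
                      lambda = 2 * EM[r, cc],
                      beta = 2 * tLG_EM[r, cc],
                      psi = if (r == cc) W[r, r] else 2 * W[r, cc],
                      theta = if (r == cc) E[r, r] else 2 * E[r, cc])
  }
  list(value = value, grad = grad, Sigma = Sigma, Sinv = Sinv)
}

# data-driven start values: marker indicators serve as latent proxies;
# loadings from covariances with the proxy, structural paths from
# regressions among proxies, with mild shrinkage of variance components
#' @keywords internal
#' @noRd
sem_start_values <- function(spec, X) {
  tab <- spec$param_table
  m <- ncol(spec$lambda$value)
  markers <- vapply(seq_len(m), function(k) {
    fixed <- which(!spec$lambda$free[, k] & spec$lambda$value[, k] != 0)
    if (length(fixed)) fixed[1] else which(spec$lambda$value[, k] != 0)[1]
  }, integer(1))
  Pr <- X[, markers, drop = FALSE]
  Cp <- stats::cov(Pr)
  start <- spec_start_vector(spec)
  for (i in seq_len(nrow(tab))) {
    r <- tab$row[i]; cc <- tab$col[i]
    start[i] <- switch(tab$matrix[i],
      lambda = {
        s <- stats::cov(X[, r], Pr[, cc]) / Cp[cc, cc]
        if (is.finite(s) && abs(s) < 10) s else 1
      },
      beta = {
        preds <- which(spec$beta$free[r, ] | spec$beta$value[r, ] != 0)
        cf <- tryCatch(stats::coef(stats::lm(Pr[, r] ~ Pr[, preds] - 1)),
                       error = function(e) NULL)
        v <- if (is.null(cf)) 0 else cf[match(cc, preds)]
        if (is.finite(v)) v else 0
      },
      psi = {
        if (r == cc) max(0.05, 0.6 * Cp[r, r]) else 0.5 * Cp[r, cc]
      },
      theta = {
        if (r == cc) max(0.05, 0.3 * stats::var(X[, r])) else 0
      })
  }
  start
}

#' Fit a structural equation model by normal-theory maximum likelihood
#'
#' Minimises the ML discrepancy
#' `F_ML(theta) = log|Sigma(theta)| + tr(S Sigma(theta)^-1) - log|S| - p`
#' (S the ML sample covariance, divisor n) by quasi-Newton with an analytic
#' gradient, from data-driven start values. Naive standard errors come from
#' the inverse observed information of the casewise log-likelihood; with
#' `robust = TRUE` the information matrix of the scores is estimated from
#' casewise score outer products (scores by central finite differences of the
#' casewise log-likelihood) and sandwich standard errors
#' `sqrt((1/n)(H^-1 I H^-1)_jj)` are added. A fit is flagged non-converged
#' (with a reason code) on optimizer failure, gradient norm above tolerance,
#' non-positive-definite implied covariance, or a negative variance estimate
#' (Heywood case); such replications are meant to be excluded from power fits.
#'
#' @param data numeric matrix or data frame of indicator scores (columns must
#'   cover the spec's `indicator_names`).
#' @param spec an [sem_spec()].
#' @param robust also compute sandwich standard errors.
#' @param grad_tol convergence tolerance on the gradient norm of `F_ML`.
#'
#' @return An object of class `mspe_sem_fit`: label-indexed `estimates`,
#'   `se_naive`, `se_robust` (or `NULL`), `loglik`, `fmin`, `converged`,
#'   `reason`, `n`, `gradient_norm`, and the `spec`.
#' @export
fit_ml <- function(data, spec, robust = FALSE, grad_tol = 1e-6) {
  stopifnot(inherits(spec, "mspe_sem_spec"))
  X <- as.matrix(as.data.frame(data)[, spec$indicator_names, drop = FALSE])
  n <- nrow(X); p <- ncol(X)
  if (n <= p) mspe_abort("need n > number of indicators", "mspe_spec_error")
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / n
  chS <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(chS)) {
    mspe_abort("sample covariance is not positive definite", "mspe_spec_error")
  }
  logdetS <- 2 * sum(log(diag(chS)))
  check_identification(spec)

  start <- sem_start_values(spec, X)
  fn <- function(th) {
    v <- fml_objective(th, spec, S, logdetS, want_grad = FALSE)$value
    if (!is.finite(v)) 1e10 else v
  }
  gr <- function(th) {
    o <- fml_objective(th, spec, S, logdetS)
    if (!is.finite(o$value)) rep(0, length(th)) else o$grad
  }
  opt <- stats::nlminb(start, fn, gradient = gr,
                       control = list(iter.max = 500, eval.max = 1000,
                                      rel.tol = 1e-12, x.tol = 1e-12))
  # Newton polish: nlminb stops on relative-tolerance criteria, a few
  # damped Newton steps push the gradient norm to the stated tolerance
  est <- opt$par
  o <- fml_objective(est, spec, S, logdetS)
  gnorm <- if (is.finite(o$value)) sqrt(sum(o$grad^2)) else Inf
  for (k in seq_len(8)) {
    if (!is.finite(gnorm) || gnorm < grad_tol / 10) break
    H <- tryCatch(stats::optimHess(est, fn, gr), error = function(e) NULL)
    step <- if (!is.null(H)) {
      tryCatch(solve(H, o$grad), error = function(e) NULL)
    }
    if (is.null(step) || !all(is.finite(step))) break
    t_ <- 1
    improved <- FALSE
    while (t_ > 1e-4) {
      o_new <- fml_objective(est - t_ * step, spec, S, logdetS)
      if (is.finite(o_new$value) &&
          (o_new$value < o$value ||
           sqrt(sum(o_new$grad^2)) < gnorm)) {
        est <- est - t_ * step
        o <- o_new
        gnorm <- sqrt(sum(o$grad^2))
        improved <- TRUE
        break
      }
      t_ <- t_ / 2
    }
    if (!improved) break
  }
  tab <- spec$param_table
  names(est) <- tab$label

  reason <- NULL
  if (!is.finite(o$value)) {
    reason <- "non_pd_sigma"
  } else if (gnorm >= grad_tol) {
    reason <- "max_iterations"
  } else {
    mats <- spec_matrices_at(spec, est)
    if (any(diag(mats$psi)[diag(spec$psi$free)] < 0) ||
        any(diag(mats$theta)[diag(spec$theta$free)] < 0)) {
      reason <- "heywood"
    }
  }
  converged <- is.null(reason)

  loglik <- if (is.finite(o$value)) {
    -n / 2 * (o$value + logdetS + p + p * log(2 * pi))
  } else {
    NA_real_
  }

  se_naive <- rep(NA_real_, length(est))
  se_robust <- NULL
  Hbar <- NULL
  if (converged) {
    HF <- stats::optimHess(est, fn, gr)
    Hbar <- (HF + t(HF)) / 4  # per-observation Hessian of -loglik: HF/2
    Hinv <- tryCatch(solve(Hbar), error = function(e) NULL)
    if (is.null(Hinv) || any(diag(Hinv) <= 0)) {
      converged <- FALSE
      reason <- "information_not_pd"
    } else {
      se_naive <- sqrt(diag(Hinv) / n)
      if (robust) {
        sc <- casewise_scores(est, spec, Xc)
        I_hat <- crossprod(sc) / n
        SW <- Hinv %*% I_hat %*% Hinv
        se_robust <- sqrt(pmax(diag(SW), 0) / n)
        names(se_robust) <- tab$label
      }
    }
  }
  names(se_naive) <- tab$label

  structure(list(estimates = est, se_naive = se_naive, se_robust = se_robust,
                 loglik = loglik, fmin = o$value, converged = converged,
                 reason = reason %||% "ok", n = n,
                 gradient_norm = gnorm, spec = spec),
            class = "mspe_sem_fit")
}

# casewise log-likelihood contributions at theta (fixed saturated mean)
#' @keywords internal
#' @noRd
casewise_loglik <- function(theta_vec, spec, Xc) {
  o <- fml_objective(theta_vec, spec, crossprod(Xc) / nrow(Xc),
                     0, want_grad = FALSE)
  if (!is.finite(o$value %||% NA_real_)) return(rep(NA_real_, nrow(Xc)))
  ch <- chol(o$Sigma)
  q <- rowSums((Xc %*% chol2inv(ch))* Xc)
  -0.5 * (ncol(Xc) * log(2 * pi) + 2 * sum(log(diag(ch))) + q)
}

# central finite differences, step 1e-6 * max(1, |theta_j|)
#' @keywords internal
#' @noRd
casewise_scores <- function(theta_vec, spec, Xc) {
  q <- length(theta_vec)
  sc <- matrix(NA_real_, nrow(Xc), q)
  for (j in seq_len(q)) {
    h <- 1e-6 * max(1, abs(theta_vec[j]))
    up <- theta_vec; up[j] <- up[j] + h
    dn <- theta_vec; dn[j] <- dn[j] - h
    sc[, j] <- (casewise_loglik(up, spec, Xc) -
                  casewise_loglik(dn, spec, Xc)) / (2 * h)
  }
  sc
}

#' @export
print.mspe_sem_fit <- function(x, ...) {
  cat(sprintf("SEM ML fit: n = %d, F_ML = %.6g, converged: %s (%s)\n",
              x$n, x$fmin, x$converged, x$reason))
  df <- data.frame(estimate = x$estimates, se_naive = x$se_naive)
  if (!is.null(x$se_robust)) df$se_robust <- x$se_robust
  print(round(df, 4))
  invisible(x)
}

#' z-test for one model parameter
#'
#' Computes `z = estimate / SE` (naive or sandwich standard error) and the
#' significance decision. The one-sided test multiplies the z-value by the
#' hypothesised sign of the effect and rejects when the result exceeds
#' `q_{1-alpha}`; the two-sided test rejects when `|z| > q_{1-alpha/2}`.
#'
#' @param fit an [fit_ml()] result (must have converged).
#' @param label parameter label; defaults to the spec's focal parameter.
#' @param sided `"two_sided"` or `"one_sided"`.
#' @param alpha test level.
#' @param robust use sandwich standard errors (must have been computed).
#' @param hypothesized_sign sign of the effect under H1 (one-sided test).
#'
#' @return An object of class `mspe_z_test` with `label`, `z_value`,
#'   `p_one_sided`, `p_two_sided`, `significant`.
#' @export
z_test <- function(fit, label = NULL, sided = c("two_sided", "one_sided"),
                   alpha = 0.05, robust = FALSE, hypothesized_sign = 1) {
  sided <- match.arg(sided)
  stopifnot(inherits(fit, "mspe_sem_fit"))
  if (!fit$converged) {
    mspe_abort("z-test requires a converged fit", "mspe_fit_error")
  }
  label <- label %||% fit$spec$focal_label
  if (is.null(label) || !(label %in% names(fit$estimates))) {
    mspe_abort(sprintf("unknown parameter label '%s'", label %||% "<null>"),
               "mspe_lookup_error")
  }
  se <- if (robust) {
    if (is.null(fit$se_robust)) {
      mspe_abort("robust SEs were not computed (refit with robust = TRUE)",
                 "mspe_fit_error")
    }
    fit$se_robust[[label]]
  } else {
    fit$se_naive[[label]]
  }
  z <- fit$estimates[[label]] / se
  zs <- sign(hypothesized_sign) * z
  p_one <- stats::pnorm(zs, lower.tail = FALSE)
  p_two <- 2 * min(stats::pnorm(z), stats::pnorm(-z))
  significant <- if (sided == "one_sided") {
    zs > stats::qnorm(1 - alpha)
  } else {
    abs(z) > stats::qnorm(1 - alpha / 2)
  }
  structure(list(label = label, z_value = z, p_one_sided = p_one,
                 p_two_sided = p_two, significant = as.integer(significant),
                 sided = sided, alpha = alpha, robust = robust),
            class = "mspe_z_test")
}

#' @export
print.mspe_z_test <- function(x, ...) {
  cat(sprintf("z-test for %s: z = %.3f, p(%s) = %.4g -> %s at alpha = %g\n",
              x$label, x$z_value, x$sided,
              if (x$sided == "one_sided") x$p_one_sided else x$p_two_sided,
              if (x$significant == 1) "significant" else "not significant",
              x$alpha))
  invisible(x)
}
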