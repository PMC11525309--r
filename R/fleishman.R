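# Fleishman cubic-polynomial transforms and the Vale-Maurelli multivariate
# extension for generating non-normal data with target third and fourth
# moments and a target correlation structure.

# Moments of Y = a + bZ + cZ^2 + dZ^3 with a = -c and Z standard normal:
# variance, skewness and EXCESS kurtosis as functions of (b, c, d).
#' @keywords internal
#' @noRd
fleishman_moments <- function(b, c, d) {
  v <- b^2 + 6 * b * d + 2 * c^2 + 15 * d^2
  s <- 2 * c * (b^2 + 24 * b * d + 105 * d^2 + 2)
  k <- 24 * (b * d + c^2 * (1 + b^2 + 28 * b * d) +
               d^2 * (12 + 48 * b * d + 141 * c^2 + 225 * d^2))
  stats::setNames(c(v, s, k), c("var", "skew", "exkurt"))
}

#' Solve for Fleishman polynomial coefficients
#'
#' Finds `(a, b, c, d)` with `a = -c` such that `Y = a + bZ + cZ^2 + dZ^3`
#' (Z standard normal) has mean 0, variance 1, and the requested skewness and
#' excess kurtosis, by Newton iteration on the three moment equations
#' (residual tolerance 1e-10). Note the kurtosis argument is EXCESS kurtosis
#' (normal = 0), the convention of the Vale-Maurelli literature.
#'
#' @param skew target skewness.
#' @param exkurt target excess kurtosis; must satisfy the feasibility bound
#'   `exkurt >= skew^2 - 2` (pairs below it admit no distribution at all),
#'   and in practice roughly `exkurt >= 1.64 skew^2 - 1.23` for a Fleishman
#'   cubic to exist.
#' @param allow_boundary if `TRUE`, a target outside the representable
#'   region does not raise an error: the least-squares boundary solution is
#'   returned (with a warning reporting the moments actually achieved, in an
#'   `"achieved"` attribute). Off by default - infeasible targets error.
#'
#' @return Named numeric vector `c(a, b, c, d)`.
#' @examples
#' cf <- fleishman_coefficients(1.7, 7.2)
#' @export
fleishman_coefficients <- function(skew, exkurt, allow_boundary = FALSE) {
  key <- paste(skew, exkurt, allow_boundary, sep = "|")
  cached <- .fleishman_cache[[key]]
  if (!is.null(cached)) return(cached)
  if (exkurt < skew^2 - 2) {
    mspe_abort(sprintf(
      "(skew = %g, exkurt = %g) is infeasible: need exkurt >= skew^2 - 2",
      skew, exkurt), "mspe_feasibility_error")
  }
  target <- c(1, skew, exkurt)
  resid <- function(x) fleishman_moments(x[1], x[2], x[3]) - target
  starts <- list(c(1, skew / 6, 0.01), c(0.9, 0.2, 0.1),
                 c(0.8, skew / 8, 0.05), c(1, 0, 0))
  for (x in starts) {
    ok <- TRUE
    for (it in 1:200) {
      r <- resid(x)
      if (max(abs(r)) < 1e-12) break
      J <- matrix(0, 3, 3)
      h <- 1e-7
      for (j in 1:3) {
        e <- numeric(3); e[j] <- h
        J[, j] <- (resid(x + e) - resid(x - e)) / (2 * h)
      }
      step <- tryCatch(solve(J, r), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) { ok <- FALSE; break }
      t_ <- 1
      while (t_ > 1e-8 &&
             (!all(is.finite(resid(x - t_ * step))) ||
              sum(resid(x - t_ * step)^2) > sum(r^2))) {
        t_ <- t_ / 2
      }
      x <- x - t_ * step
    }
    if (ok && max(abs(resid(x))) < 1e-10 && x[1] > 0) {
      out <- c(a = -x[2], b = x[1], c = x[2], d = x[3])
      .fleishman_cache[[key]] <- out
      return(out)
    }
  }
  if (allow_boundary) {
    # unit variance is held (heavily weighted); the compromise is confined
    # to the unattainable third/fourth moments
    ss <- function(x) { r <- resid(x); 1e6 * r[1]^2 + r[2]^2 + r[3]^2 }
    best <- NULL
    for (x0 in starts) {
      o <- stats::optim(x0, ss, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
      o <- stats::optim(o$par, ss, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
      if (is.null(best) || o$value < best$value) best <- o
    }
    x <- best$par
    ach <- fleishman_moments(x[1], x[2], x[3])
    warning(sprintf(
      paste("(skew = %g, exkurt = %g) is not Fleishman-representable;",
            "using the least-squares boundary solution with achieved",
            "skew = %.3f, exkurt = %.3f"),
      skew, exkurt, ach["skew"], ach["exkurt"]), call. = FALSE)
    out <- structure(c(a = -x[2], b = x[1], c = x[2], d = x[3]),
                     achieved = ach)
    .fleishman_cache[[key]] <- out
    return(out)
  }
  mspe_abort(sprintf(
    paste("Fleishman solver did not converge for (skew = %g, exkurt = %g);",
          "the pair lies outside (or too close to) the",
          "Fleishman-representable region - try a larger kurtosis for the",
          "given skewness, or set allow_boundary = TRUE for the",
          "least-squares boundary solution"),
    skew, exkurt), "mspe_feasibility_error")
}

# solved-coefficient memo (one warning per boundary target, not per draw)
.fleishman_cache <- new.env(parent = emptyenv())

#' Intermediate correlation matrix for Vale-Maurelli generation
#'
#' For each variable pair, solves the cubic relating the pre-polynomial
#' (normal) correlation `rho` to the post-polynomial target correlation `r`:
#' `r = rho (b_i b_j + 3 b_i d_j + 3 d_i b_j + 9 d_i d_j) +
#' rho^2 (2 c_i c_j) + rho^3 (6 d_i d_j)`. The real root in \[-1, 1\] is
#' taken; the assembled matrix must be positive definite (no smoothing is
#' applied silently).
#'
#' @param target_corr target correlation matrix of the transformed variables.
#' @param fleishman list of per-variable coefficient vectors from
#'   [fleishman_coefficients()].
#'
#' @return The intermediate correlation matrix for the underlying normals.
#' @export
vm_intermediate_correlation <- function(target_corr, fleishman) {
  k <- nrow(target_corr)
  stopifnot(length(fleishman) == k)
  if (any(eigen(target_corr, symmetric = TRUE, only.values = TRUE)$values
          <= 0)) {
    mspe_abort("target correlation matrix is not positive definite",
               "mspe_feasibility_error")
  }
  R <- diag(k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ci <- fleishman[[i]]; cj <- fleishman[[j]]
      lin <- ci["b"] * cj["b"] + 3 * ci["b"] * cj["d"] +
        3 * ci["d"] * cj["b"] + 9 * ci["d"] * cj["d"]
      quad <- 2 * ci["c"] * cj["c"]
      cub <- 6 * ci["d"] * cj["d"]
      roots <- polyroot(c(-target_corr[i, j], lin, quad, cub))
      real <- Re(roots[abs(Im(roots)) < 1e-8])
      real <- real[real >= -1 & real <= 1]
      if (length(real) == 0) {
        mspe_abort(sprintf(
          "no admissible intermediate correlation for pair (%d, %d)", i, j),
          "mspe_feasibility_error")
      }
      R[i, j] <- R[j, i] <- real[which.min(abs(real - target_corr[i, j]))]
    }
  }
  if (any(eigen(R, symmetric = TRUE, only.values = TRUE)$values <= 1e-12)) {
    mspe_abort("assembled intermediate correlation matrix is not positive definite",
               "mspe_feasibility_error")
  }
  R
}

#' Generate multivariate non-normal data (Vale-Maurelli)
#'
#' Draws correlated standard normals with the solved intermediate correlation
#' and pushes each column through its Fleishman polynomial, yielding
#' variables with mean 0, variance 1, the target skewness/excess kurtosis,
#' and the target correlation matrix. Uses the current RNG state (seed
#' management is the caller's job).
#'
#' @param n number of draws.
#' @param target_corr target correlation matrix (k x k).
#' @param skew,exkurt length-k target moment vectors.
#' @param allow_boundary passed to [fleishman_coefficients()].
#' @return An `n x k` matrix.
#' @export
generate_vale_maurelli <- function(n, target_corr, skew, exkurt,
                                   allow_boundary = FALSE) {
  k <- nrow(target_corr)
  stopifnot(length(skew) == k, length(exkurt) == k)
  coefs <- lapply(seq_len(k), function(i) {
    fleishman_coefficients(skew[i], exkurt[i], allow_boundary)
  })
  R <- vm_intermediate_correlation(target_corr, coefs)
  Z <- matrix(stats::rnorm(n * k), n, k) %*% chol(R)
  out <- matrix(0, n, k)
  for (i in seq_len(k)) {
    cf <- coefs[[i]]
    out[, i] <- cf["a"] + cf["b"] * Z[, i] + cf["c"] * Z[, i]^2 +
      cf["d"] * Z[, i]^3
  }
  out
}
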