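#' Specify a structural equation model in matrix form
#'
#' A model is held as four patterned matrices in an all-latent (LISREL-style)
#' parameterisation with every latent variable collected in one vector:
#' `lambda` (indicator loadings, p x m), `beta` (latent regressions among all
#' latents, m x m, acyclic), `psi` (covariance of latent exogenous variables
#' and structural residuals, m x m symmetric) and `theta` (indicator residual
#' covariance, p x p symmetric, diagonal by default). Each matrix is given as
#' a value matrix plus a logical `free` pattern of the same shape; values of
#' free entries are used as start values. The implied indicator covariance is
#' `Sigma = Lambda (I - B)^-1 Psi (I - B)^-T Lambda' + Theta`. Identification
#' uses the marker method (one loading per latent fixed, typically to 1).
#'
#' Free parameters are labelled lavaan-style (`"eta1~xi1"`, `"xi1=~x2"`,
#' `"x1~~x1"`); `focal_label` names the parameter whose z-test drives the
#' power analysis.
#'
#' @param lambda,beta,psi,theta lists with elements `value` (numeric matrix)
#'   and `free` (logical matrix of the same dimension).
#' @param latent_names,indicator_names dimension names.
#' @param focal_label label of the focal parameter (optional).
#'
#' @return An object of class `mspe_sem_spec`.
#' @seealso [study1_spec()] for a ready-made example, [implied_moments()],
#'   [fit_ml()].
#' @export
sem_spec <- function(lambda, beta, psi, theta,
                     latent_names = NULL, indicator_names = NULL,
                     focal_label = NULL) {
  p <- nrow(lambda$value); m <- ncol(lambda$value)
  if (is.null(latent_names)) latent_names <- paste0("f", seq_len(m))
  if (is.null(indicator_names)) indicator_names <- paste0("v", seq_len(p))
  stopifnot(all(dim(beta$value) == c(m, m)), all(dim(psi$value) == c(m, m)),
            all(dim(theta$value) == c(p, p)))
  for (mt in list(lambda, beta, psi, theta)) {
    stopifnot(is.matrix(mt$value), is.matrix(mt$free),
              all(dim(mt$value) == dim(mt$free)))
  }
  if (!all(is.finite(psi$value[!psi$free])) ||
      !all(is.finite(beta$value[!beta$free]))) {
    mspe_abort("fixed parameter values must be finite", "mspe_spec_error")
  }
  g <- tryCatch(solve(diag(m) - beta$value), error = function(e) NULL)
  if (is.null(g)) {
    mspe_abort("I - beta is singular: structural system is not solvable",
               "mspe_spec_error")
  }
  spec <- structure(list(lambda = lambda, beta = beta, psi = psi,
                         theta = theta, latent_names = latent_names,
                         indicator_names = indicator_names,
                         focal_label = focal_label),
                    class = "mspe_sem_spec")
  spec$param_table <- build_param_table(spec)
  if (!is.null(focal_label) && !(focal_label %in% spec$param_table$label)) {
    mspe_abort(sprintf("focal_label '%s' is not a free parameter", focal_label),
               "mspe_spec_error")
  }
  spec
}

# enumerate free parameters: loadings, structural paths, psi lower triangle,
# theta lower triangle (column-major within each block)
#' @keywords internal
#' @noRd
build_param_table <- function(spec) {
  lat <- spec$latent_names; ind <- spec$indicator_names
  rows <- list()
  fr <- which(spec$lambda$free, arr.ind = TRUE)
  if (nrow(fr)) {
    rows[[length(rows) + 1L]] <- data.frame(
      matrix = "lambda", row = fr[, 1], col = fr[, 2],
      label = paste0(lat[fr[, 2]], "=~", ind[fr[, 1]]))
  }
  fr <- which(spec$beta$free, arr.ind = TRUE)
  if (nrow(fr)) {
    rows[[length(rows) + 1L]] <- data.frame(
      matrix = "beta", row = fr[, 1], col = fr[, 2],
      label = paste0(lat[fr[, 1]], "~", lat[fr[, 2]]))
  }
  fr <- which(spec$psi$free & lower.tri(spec$psi$free, diag = TRUE),
              arr.ind = TRUE)
  if (nrow(fr)) {
    rows[[length(rows) + 1L]] <- data.frame(
      matrix = "psi", row = fr[, 1], col = fr[, 2],
      label = paste0(lat[fr[, 2]], "~~", lat[fr[, 1]]))
  }
  fr <- which(spec$theta$free & lower.tri(spec$theta$free, diag = TRUE),
              arr.ind = TRUE)
  if (nrow(fr)) {
    rows[[length(rows) + 1L]] <- data.frame(
      matrix = "theta", row = fr[, 1], col = fr[, 2],
      label = paste0(ind[fr[, 2]], "~~", ind[fr[, 1]]))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}

#' @keywords internal
#' @noRd
spec_start_vector <- function(spec) {
  tab <- spec$param_table
  vapply(seq_len(nrow(tab)), function(i) {
    spec[[tab$matrix[i]]]$value[tab$row[i], tab$col[i]]
  }, numeric(1))
}

# write a parameter vector into the value matrices (symmetric fill for
# psi/theta) and return the four matrices
#' @keywords internal
#' @noRd
spec_matrices_at <- function(spec, theta_vec) {
  tab <- spec$param_table
  stopifnot(length(theta_vec) == nrow(tab))
  L <- spec$lambda$value; B <- spec$beta$value
  P <- spec$psi$value; Th <- spec$theta$value
  for (i in seq_len(nrow(tab))) {
    r <- tab$row[i]; cc <- tab$col[i]; v <- theta_vec[i]
    switch(tab$matrix[i],
           lambda = { L[r, cc] <- v },
           beta = { B[r, cc] <- v },
           psi = { P[r, cc] <- v; P[cc, r] <- v },
           theta = { Th[r, cc] <- v; Th[cc, r] <- v })
  }
  list(lambda = L, beta = B, psi = P, theta = Th)
}

#' Model-implied indicator covariance matrix
#'
#' Evaluates `Sigma(theta) = Lambda (I-B)^-1 Psi (I-B)^-T Lambda' + Theta`
#' at a parameter vector (ordered as in the spec's parameter table; defaults
#' to the spec's stored values).
#'
#' @param spec an [sem_spec()].
#' @param theta optional free-parameter vector.
#' @return A symmetric p x p covariance matrix with indicator dimnames.
#' @export
implied_moments <- function(spec, theta = NULL) {
  stopifnot(inherits(spec, "mspe_sem_spec"))
  if (is.null(theta)) theta <- spec_start_vector(spec)
  mats <- spec_matrices_at(spec, theta)
  m <- ncol(mats$lambda)
  G <- tryCatch(solve(diag(m) - mats$beta), error = function(e) NULL)
  if (is.null(G)) mspe_abort("I - beta is singular", "mspe_spec_error")
  LG <- mats$lambda %*% G
  Sigma <- LG %*% mats$psi %*% t(LG) + mats$theta
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- list(spec$indicator_names, spec$indicator_names)
  Sigma
}

# Jacobian of vech(Sigma) w.r.t. the free parameters, used for the local
# identification (full column rank) check
#' @keywords internal
#' @noRd
implied_jacobian <- function(spec, theta = NULL) {
  if (is.null(theta)) theta <- spec_start_vector(spec)
  mats <- spec_matrices_at(spec, theta)
  p <- nrow(mats$lambda); m <- ncol(mats$lambda)
  G <- solve(diag(m) - mats$beta)
  A <- G %*% mats$psi %*% t(G)
  LG <- mats$lambda %*% G
  M <- mats$lambda %*% A
  lo <- lower.tri(matrix(0, p, p), diag = TRUE)
  tab <- spec$param_table
  J <- matrix(0, sum(lo), nrow(tab))
  for (i in seq_len(nrow(tab))) {
    r <- tab$row[i]; cc <- tab$col[i]
    dS <- matrix(0, p, p)
    switch(tab$matrix[i],
           lambda = {
             dS[r, ] <- dS[r, ] + M[, cc]
             dS[, r] <- dS[, r] + M[, cc]
           },
           beta = {
             u <- LG[, r]; v <- M[, cc]
             dS <- u %o% v + v %o% u
           },
           psi = {
             d <- if (r == cc) LG[, r] %o% LG[, r] else
               LG[, r] %o% LG[, cc] + LG[, cc] %o% LG[, r]
             dS <- d
           },
           theta = {
             dS[r, cc] <- dS[r, cc] + 1
             dS[cc, r] <- dS[cc, r] + 1
             if (r == cc) dS[r, cc] <- 1
           })
    J[, i] <- dS[lo]
  }
  J
}

#' @keywords internal
#' @noRd
check_identification <- function(spec, theta = NULL) {
  J <- implied_jacobian(spec, theta)
  if (ncol(J) > nrow(J)) {
    mspe_abort(sprintf(
      "model has %d free parameters but only %d distinct moments",
      ncol(J), nrow(J)), "mspe_spec_error")
  }
  if (qr(J)$rank < ncol(J)) {
    mspe_abort("model not locally identified (implied-moment Jacobian is rank deficient)",
               "mspe_spec_error")
  }
  invisible(TRUE)
}

#' Linear SEM used in the first simulation study
#'
#' Builds the four-latent linear SEM with exogenous factors `xi1`, `xi2`
#' (correlation `phi12`) and endogenous factors `eta1`, `eta2`, structural
#' equations `eta1 ~ xi1 + xi2` and `eta2 ~ eta1 + xi1 + xi2`, and three
#' indicators per latent with population loadings `c(1, .8, .7)` (marker
#' loading fixed to 1, remaining loadings free). Indicator residual
#' covariance is diagonal and free; exogenous variances/covariance and the
#' two structural residual variances are free. The focal parameter defaults
#' to the path `eta1~xi1` (population value .2).
#'
#' Supplied values are used as start values for free parameters, so the
#' builder doubles as the population-parameter container for data generation.
#'
#' @param loadings length-3 population loading pattern per latent.
#' @param gamma11,gamma12,beta21,gamma21,gamma22 structural start values.
#' @param phi12 exogenous latent correlation start value.
#' @param zeta_var length-2 structural residual variances (start values).
#' @param theta_resid indicator residual variance (scalar or length 12).
#' @param focal_label focal parameter label.
#' @return An `mspe_sem_spec`.
#' @export
study1_spec <- function(loadings = c(1, .8, .7),
                        gamma11 = .2, gamma12 = .5, beta21 = .3,
                        gamma21 = .4, gamma22 = .3, phi12 = .5,
                        zeta_var = c(.55, .45), theta_resid = .36,
                        focal_label = "eta1~xi1") {
  lat <- c("xi1", "xi2", "eta1", "eta2")
  ind <- c(paste0("x", 1:6), paste0("y", 1:6))
  p <- 12L; m <- 4L
  Lv <- matrix(0, p, m); Lf <- matrix(FALSE, p, m)
  for (k in 1:4) {
    rows <- (k - 1) * 3 + 1:3
    Lv[rows, k] <- loadings
    Lf[rows, k] <- c(FALSE, TRUE, TRUE)  # marker fixed
  }
  Bv <- matrix(0, m, m); Bf <- matrix(FALSE, m, m)
  Bv[3, 1] <- gamma11; Bv[3, 2] <- gamma12
  Bv[4, 3] <- beta21; Bv[4, 1] <- gamma21; Bv[4, 2] <- gamma22
  Bf[3, 1] <- Bf[3, 2] <- Bf[4, 3] <- Bf[4, 1] <- Bf[4, 2] <- TRUE
  Pv <- diag(c(1, 1, zeta_var))
  Pv[1, 2] <- Pv[2, 1] <- phi12
  Pf <- matrix(FALSE, m, m)
  Pf[1, 1] <- Pf[2, 2] <- Pf[3, 3] <- Pf[4, 4] <- TRUE
  Pf[2, 1] <- Pf[1, 2] <- TRUE
  Tv <- diag(rep_len(theta_resid, p))
  Tf <- diag(TRUE, p)
  sem_spec(list(value = Lv, free = Lf), list(value = Bv, free = Bf),
           list(value = Pv, free = Pf), list(value = Tv, free = Tf),
           latent_names = lat, indicator_names = ind,
           focal_label = focal_label)
}

#' @export
print.mspe_sem_spec <- function(x, ...) {
  cat(sprintf("SEM spec: %d indicators, %d latents, %d free parameters\n",
              nrow(x$lambda$value), ncol(x$lambda$value),
              nrow(x$param_table)))
  if (!is.null(x$focal_label)) cat("  focal parameter:", x$focal_label, "\n")
  invisible(x)
}
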