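# Synthetic-data generators for the two study designs: a linear SEM and a
# quadratic/interaction SEM (QISEM) sharing the same structural skeleton
#   eta1 = g11 xi1 + g12 xi2 + g13 xi1*xi2 + zeta1   (g13 = 0: linear)
#   eta2 = b21 eta1 + g21 xi1 + g22 xi2 + zeta2
# with standardized latent variables and three indicators per latent.

#' Configuration for the synthetic-data generator
#'
#' Collects the population quantities of the generating model. The defaults
#' are the study conditions used throughout: structural coefficients
#' `.2/.5/.3/.4/.3`, interaction effect `.1` (QISEM only), exogenous latent
#' correlation `.5`, loadings `c(1, .8, .7)` per latent, and equal indicator
#' residual variances `.36` (giving coefficient omega of about .85 per
#' scale). Structural residual variances are not set here: they are solved by
#' [solve_standardizing_residuals()] so every latent variable has unit
#' variance.
#'
#' @param model `"linear_sem"` (forces `gamma13 = 0`) or `"qisem"`.
#' @param gamma11,gamma12,gamma13,beta21,gamma21,gamma22 structural
#'   coefficients (`gamma13` is the latent interaction effect).
#' @param phi12 correlation of the exogenous latents.
#' @param loadings length-3 loading vector applied to every latent.
#' @param theta_residuals indicator residual variance, scalar or length 12.
#' @param distribution `"normal"`, or a list
#'   `list(type = "vale_maurelli", skew =, exkurt =, placement =)` where
#'   `placement` is `"latent"` (non-normal exogenous factors; `skew`/`exkurt`
#'   of length 2) or `"manifest"` (non-normal indicators, linear SEM only;
#'   length 12).
#'
#' @return An object of class `mspe_generation_config`.
#' @export
generation_config <- function(model = c("linear_sem", "qisem"),
                              gamma11 = .2, gamma12 = .5, gamma13 = .1,
                              beta21 = .3, gamma21 = .4, gamma22 = .3,
                              phi12 = .5, loadings = c(1, .8, .7),
                              theta_residuals = .36,
                              distribution = "normal") {
  model <- match.arg(model)
  if (model == "linear_sem") gamma13 <- 0
  if (is.character(distribution)) {
    distribution <- match.arg(distribution, "normal")
  } else {
    stopifnot(is.list(distribution), distribution$type == "vale_maurelli")
    distribution$placement <- distribution$placement %||% "latent"
    nd <- if (distribution$placement == "latent") 2L else 12L
    if (length(distribution$skew) != nd || length(distribution$exkurt) != nd) {
      mspe_abort(sprintf(
        "vale_maurelli with placement '%s' needs %d skew/exkurt values",
        distribution$placement, nd), "mspe_config_error")
    }
    if (distribution$placement == "manifest" && model != "linear_sem") {
      mspe_abort("manifest-level non-normality is only supported for the linear SEM",
                 "mspe_config_error")
    }
  }
  if (abs(phi12) >= 1) mspe_abort("phi12 must lie in (-1, 1)", "mspe_config_error")
  if (length(loadings) != 3) {
    mspe_abort("loadings must have length 3 (three indicators per latent)",
               "mspe_config_error")
  }
  structure(list(model = model, gamma11 = gamma11, gamma12 = gamma12,
                 gamma13 = gamma13, beta21 = beta21, gamma21 = gamma21,
                 gamma22 = gamma22, phi12 = phi12, loadings = loadings,
                 theta_residuals = rep_len(theta_residuals, 12),
                 distribution = distribution),
            class = "mspe_generation_config")
}

#' Linear-SEM study configuration
#'
#' The linear SEM condition: structural model `eta1 = .2 xi1 + .5 xi2 +
#' zeta1`, `eta2 = .3 eta1 + .4 xi1 + .3 xi2 + zeta2`, focal parameter the
#' path `xi1 -> eta1` (.2).
#' @param ... overrides passed to [generation_config()].
#' @return An `mspe_generation_config`.
#' @export
study1_config <- function(...) {
  generation_config(model = "linear_sem", ...)
}

#' QISEM study configuration
#'
#' The interaction condition: `eta1 = .2 xi1 + .5 xi2 + .1 xi1*xi2 + zeta1`,
#' focal parameter the interaction effect (.1). With
#' `nonnormal = TRUE` the latent predictors are generated by the
#' Vale-Maurelli transform with skewness 1.7/2.3 and excess kurtosis 7.2/6.5.
#' @param nonnormal use the non-normal latent-predictor condition.
#' @param ... overrides passed to [generation_config()].
#' @return An `mspe_generation_config`.
#' @export
study2_config <- function(nonnormal = FALSE, ...) {
  dist <- if (nonnormal) {
    # the (2.3, 6.5) pair is outside the Fleishman-representable region;
    # allow_boundary substitutes the least-squares boundary solution (with
    # one warning) so the published condition remains runnable
    list(type = "vale_maurelli", skew = c(1.7, 2.3), exkurt = c(7.2, 6.5),
         placement = "latent", allow_boundary = TRUE)
  } else {
    "normal"
  }
  generation_config(model = "qisem", distribution = dist, ...)
}

# draw exogenous latent scores according to the config's distribution
#' @keywords internal
#' @noRd
draw_xi <- function(config, n) {
  Rho <- matrix(c(1, config$phi12, config$phi12, 1), 2, 2)
  d <- config$distribution
  if (is.list(d) && d$placement == "latent") {
    generate_vale_maurelli(n, Rho, d$skew, d$exkurt,
                           isTRUE(d$allow_boundary))
  } else {
    matrix(stats::rnorm(2 * n), n, 2) %*% chol(Rho)
  }
}

#' Structural residual variances for standardized latent variables
#'
#' Solves `Var(zeta1)` and `Var(zeta2)` so that all four latent variables
#' have unit variance. Under normal exogenous factors this is analytic: the
#' centered product `xi1*xi2` is uncorrelated with `xi1` and `xi2` and has
#' variance `1 + phi12^2`, so
#' `Var(zeta1) = 1 - (g11^2 + g12^2 + 2 g11 g12 phi12 + g13^2 (1 + phi12^2))`,
#' and `Var(zeta2)` follows from the implied covariances of `eta1` with the
#' exogenous factors. Under Vale-Maurelli latent predictors the required
#' moments (including nonzero odd moments such as `E[xi1^2 xi2]`) are
#' estimated by a 1e6-draw Monte-Carlo evaluation with a fixed internal seed,
#' isolated from the caller's RNG state.
#'
#' @param config an [generation_config()].
#' @return Named vector `c(zeta1, zeta2)` of residual variances.
#' @export
solve_standardizing_residuals <- function(config) {
  stopifnot(inherits(config, "mspe_generation_config"))
  g11 <- config$gamma11; g12 <- config$gamma12; g13 <- config$gamma13
  b21 <- config$beta21; g21 <- config$gamma21; g22 <- config$gamma22
  phi <- config$phi12
  d <- config$distribution
  vm_latent <- is.list(d) && d$placement == "latent"
  key <- paste(c(g11, g12, g13, b21, g21, g22, phi, vm_latent,
                 if (vm_latent) c(d$skew, d$exkurt)), collapse = "|")
  cached <- .residual_cache[[key]]
  if (!is.null(cached)) return(cached)

  if (!vm_latent) {
    var_s1 <- g11^2 + g12^2 + 2 * g11 * g12 * phi + g13^2 * (1 + phi^2)
    # Cov(eta1, xi.) from the linear part only (product term orthogonal)
    c1 <- g11 + g12 * phi
    c2 <- g12 + g11 * phi
    var_s2part <- b21^2 * var_s1 + g21^2 + g22^2 + 2 * g21 * g22 * phi +
      2 * b21 * (g21 * c1 + g22 * c2)
  } else {
    # moments of the transformed predictors by fixed-seed Monte Carlo
    xi <- with_preserved_rng(1864502, function() draw_xi(config, 1e6))
    s1 <- g11 * xi[, 1] + g12 * xi[, 2] + g13 * xi[, 1] * xi[, 2]
    var_s1 <- stats::var(s1)
    s2part <- b21 * s1 + g21 * xi[, 1] + g22 * xi[, 2]
    var_s2part <- stats::var(s2part)
  }
  vz1 <- 1 - var_s1
  vz2 <- 1 - (var_s2part + b21^2 * vz1)
  if (vz1 < 0 || vz2 < 0) {
    mspe_abort("systematic variance exceeds 1: latent variables cannot be standardized",
               "mspe_config_error")
  }
  out <- c(zeta1 = vz1, zeta2 = vz2)
  .residual_cache[[key]] <- out
  out
}

# memo for solved residual variances (the VM branch runs a 1e6-draw
# Monte-Carlo evaluation; repeated study replications reuse the result)
.residual_cache <- new.env(parent = emptyenv())

# run fn under a fixed seed without disturbing the caller's RNG stream
#' @keywords internal
#' @noRd
with_preserved_rng <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Draw latent scores from the generating model
#'
#' Draws the exogenous factors (normal or Vale-Maurelli), computes the
#' endogenous factors from the structural equations (including the product
#' term for the QISEM), with structural residuals drawn normal at the solved
#' standardizing variances. The draw order (xi matrix, then zeta1, then
#' zeta2) is fixed, so a QISEM config with `gamma13 = 0` reproduces the
#' linear-SEM draws exactly under the same seed.
#'
#' @param config an [generation_config()].
#' @param n number of cases.
#' @param seed optional integer; if given, seeds the RNG (otherwise the
#'   current RNG state is used).
#' @return An `n x 4` matrix with columns `xi1, xi2, eta1, eta2`.
#' @export
generate_latents <- function(config, n, seed = NULL) {
  stopifnot(inherits(config, "mspe_generation_config"))
  if (!is.null(seed)) set.seed(seed)
  vz <- solve_standardizing_residuals(config)
  xi <- draw_xi(config, n)
  zeta1 <- stats::rnorm(n, sd = sqrt(vz[["zeta1"]]))
  zeta2 <- stats::rnorm(n, sd = sqrt(vz[["zeta2"]]))
  eta1 <- config$gamma11 * xi[, 1] + config$gamma12 * xi[, 2] +
    config$gamma13 * xi[, 1] * xi[, 2] + zeta1
  eta2 <- config$beta21 * eta1 + config$gamma21 * xi[, 1] +
    config$gamma22 * xi[, 2] + zeta2
  out <- cbind(xi1 = xi[, 1], xi2 = xi[, 2], eta1 = eta1, eta2 = eta2)
  out
}

#' Measurement model: latent scores to indicators
#'
#' Applies `x = Lambda xi + delta` with three indicators per latent, diagonal
#' normal residuals, and the fixed column order `x1..x3` (first latent),
#' `x4..x6` (second), `y1..y3` (third), `y4..y6` (fourth).
#'
#' @param latents `n x 4` latent score matrix (columns `xi1, xi2, eta1,
#'   eta2`).
#' @param loadings length-3 loading vector per latent.
#' @param theta_residuals residual variances, scalar or length 12 (all
#'   `>= 0`).
#' @param seed optional integer RNG seed.
#' @return An `n x 12` data frame of indicator scores.
#' @export
generate_indicators <- function(latents, loadings = c(1, .8, .7),
                                theta_residuals = .36, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(loadings) != 3) {
    mspe_abort("loadings must have length 3", "mspe_spec_error")
  }
  th <- rep_len(theta_residuals, 12)
  if (any(th < 0)) {
    mspe_abort("residual variances must be >= 0", "mspe_spec_error")
  }
  n <- nrow(latents)
  Lam <- matrix(0, 12, 4)
  for (k in 1:4) Lam[(k - 1) * 3 + 1:3, k] <- loadings
  X <- latents %*% t(Lam) +
    matrix(stats::rnorm(n * 12), n, 12) %*% diag(sqrt(th))
  colnames(X) <- c(paste0("x", 1:6), paste0("y", 1:6))
  as.data.frame(X)
}

#' Generate a full indicator-level dataset
#'
#' One seeded draw from the generating model: latent scores via
#' [generate_latents()], then indicators via [generate_indicators()]. For the
#' manifest-placement non-normal condition (linear SEM only) the indicators
#' are generated directly by the Vale-Maurelli transform targeting the
#' model-implied indicator correlation matrix and per-indicator
#' skewness/kurtosis, then scaled to the model-implied variances.
#'
#' @param config an [generation_config()].
#' @param n number of cases.
#' @param seed optional integer RNG seed.
#' @return An `n x 12` data frame of indicator scores (`x1..x6`, `y1..y6`).
#' @export
generate_dataset <- function(config, n, seed = NULL) {
  stopifnot(inherits(config, "mspe_generation_config"))
  if (!is.null(seed)) set.seed(seed)
  d <- config$distribution
  if (is.list(d) && d$placement == "manifest") {
    Sig <- population_indicator_cov(config)
    sds <- sqrt(diag(Sig))
    Rho <- stats::cov2cor(Sig)
    X <- generate_vale_maurelli(n, Rho, d$skew, d$exkurt,
                                isTRUE(d$allow_boundary)) %*% diag(sds)
    colnames(X) <- colnames(Sig)
    return(as.data.frame(X))
  }
  lat <- generate_latents(config, n)
  generate_indicators(lat, config$loadings, config$theta_residuals)
}

# population indicator covariance of the linear SEM (used for the
# manifest-placement generator and as a moment-matched fixture)
#' @keywords internal
#' @noRd
population_indicator_cov <- function(config) {
  vz <- solve_standardizing_residuals(config)
  spec <- study1_spec(loadings = config$loadings,
                      gamma11 = config$gamma11, gamma12 = config$gamma12,
                      beta21 = config$beta21, gamma21 = config$gamma21,
                      gamma22 = config$gamma22, phi12 = config$phi12,
                      zeta_var = unname(vz), theta_resid = config$theta_residuals)
  implied_moments(spec)
}
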