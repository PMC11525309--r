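# Orchestration of power studies: sample-size allocation, replication with
# per-replicate seed substreams, empirical reference power, and the
# bias/RMSE/type-I evaluation of power-curve modeling methods.

#' Allocate replication sample sizes
#'
#' `uniform_allocation(n_min, n_max)` cycles the integer grid `n_min..n_max`
#' until R values are emitted, so `R = k * grid` uses every sample size
#' exactly k times (e.g. R = 550 on 51..600 uses each once, R = 2200 each
#' four times). `four_point_allocation(n1..n4)` assigns `floor(R/4)`
#' replications to each of four sample sizes, with the remainder added to
#' the smallest.
#'
#' @param R total number of replications.
#' @param allocation an allocation created by [uniform_allocation()] or
#'   [four_point_allocation()].
#' @return Integer vector of length R (sorted).
#' @export
allocate_sample_sizes <- function(R, allocation) {
  stopifnot(inherits(allocation, "mspe_allocation"), R >= 1)
  if (allocation$type == "uniform") {
    grid <- seq.int(allocation$n_min, allocation$n_max)
    if (length(grid) < 2) mspe_abort("degenerate n range", "mspe_config_error")
    sort(grid[((seq_len(R) - 1L) %% length(grid)) + 1L])
  } else {
    ns <- allocation$ns
    counts <- rep(R %/% 4L, 4L)
    counts[1] <- counts[1] + (R - sum(counts))
    sort(rep(ns, counts))
  }
}

#' @rdname allocate_sample_sizes
#' @param n_min,n_max bounds of the integer sample-size grid.
#' @export
uniform_allocation <- function(n_min, n_max) {
  if (n_max <= n_min) mspe_abort("need n_max > n_min", "mspe_config_error")
  structure(list(type = "uniform", n_min = as.integer(n_min),
                 n_max = as.integer(n_max)), class = "mspe_allocation")
}

#' @rdname allocate_sample_sizes
#' @param n1,n2,n3,n4 the four sample sizes (strictly increasing).
#' @export
four_point_allocation <- function(n1, n2, n3, n4) {
  ns <- as.integer(c(n1, n2, n3, n4))
  if (any(diff(ns) <= 0)) {
    mspe_abort("four-point sample sizes must be strictly increasing",
               "mspe_config_error")
  }
  structure(list(type = "four_point", ns = ns), class = "mspe_allocation")
}

# Deterministic per-replicate seeds, kept below 2^31. Seeds are drawn from
# the master-seeded generator rather than computed by an arithmetic map:
# linearly related seed sequences give detectably correlated first draws
# after set.seed(), which distorts within-study binomial variability.
#' @keywords internal
#' @noRd
replicate_seeds <- function(master_seed, R) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master_seed)
  sample.int(2147483646L, R, replace = TRUE)
}

#' Configure a power study
#'
#' Bundles everything one power study needs: the data-generating
#' configuration, the analysis model, the focal parameter and test, the
#' replication budget and its allocation over sample sizes, the power target,
#' and the master seed. A custom `fit_fun(data, n)` returning
#' `list(significant =, converged =)` may replace the built-in SEM fitter so
#' external estimators (or idealized Bernoulli draws) can feed decisions in.
#'
#' @param generation an [generation_config()].
#' @param spec analysis model ([sem_spec()]); defaults to [study1_spec()]
#'   started near the generating values.
#' @param focal_label tested parameter; defaults to the spec's.
#' @param test `"two_sided"` or `"one_sided"`.
#' @param alpha z-test level.
#' @param rho target power (must be `<= .99`).
#' @param alpha_rho confidence-band error level for the lower-bound N.
#' @param R total replications (`>= 8`).
#' @param allocation a [uniform_allocation()] or [four_point_allocation()].
#' @param master_seed integer master seed; every replicate derives its own
#'   substream seed from it.
#' @param methods power-model methods to fit.
#' @param robust use sandwich standard errors in the z-test.
#' @param fit_fun optional callback `function(data, n)`.
#' @return An object of class `mspe_study_config`.
#' @export
study_config <- function(generation = study1_config(),
                         spec = NULL, focal_label = NULL,
                         test = c("two_sided", "one_sided"),
                         alpha = 0.05, rho = 0.80, alpha_rho = 0.05,
                         R = 550, allocation = uniform_allocation(51, 600),
                         master_seed = 1L,
                         methods = c("probit_sqrt", "wald_sqrt"),
                         robust = FALSE, fit_fun = NULL) {
  test <- match.arg(test)
  if (R < 8) mspe_abort("R must be at least 8", "mspe_config_error")
  if (rho > .99) {
    mspe_abort("target power rates above .99 are not evaluated",
               "mspe_cap_error")
  }
  if (is.null(spec) && is.null(fit_fun)) spec <- study1_spec()
  structure(list(generation = generation, spec = spec,
                 focal_label = focal_label %||% spec$focal_label,
                 test = test, alpha = alpha, rho = rho, alpha_rho = alpha_rho,
                 R = as.integer(R), allocation = allocation,
                 master_seed = as.integer(master_seed), methods = methods,
                 robust = robust, fit_fun = fit_fun),
            class = "mspe_study_config")
}

#' @keywords internal
#' @noRd
default_fit_fun <- function(config) {
  force(config)
  function(data, n) {
    fit <- tryCatch(fit_ml(data, config$spec, robust = config$robust),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      return(list(significant = 0L, converged = 0L))
    }
    zt <- z_test(fit, label = config$focal_label, sided = config$test,
                 alpha = config$alpha, robust = config$robust)
    list(significant = zt$significant, converged = 1L)
  }
}

#' Run one power study
#'
#' For each allocated sample size, generates a dataset (per-replicate seed
#' substream derived from the master seed), obtains a significance decision
#' (built-in SEM z-test or the config's callback), and logs a significance
#' record. All requested power-curve models are then fitted to the converged
#' records and inverted for the point and lower-bound required sample sizes.
#' Aborts if more than half of the replications fail to converge, since a
#' power fit on the remainder would be unreliable.
#'
#' @param config an [study_config()].
#' @return A list of class `mspe_power_study`: `records`, `fits` (one
#'   `mspe_power_fit` per method), `results` (one `mspe_samplesize` per
#'   invertible method), `nonconvergence_rate`, `config`.
#' @export
run_power_study <- function(config) {
  stopifnot(inherits(config, "mspe_study_config"))
  ns <- allocate_sample_sizes(config$R, config$allocation)
  fit_fun <- config$fit_fun %||% default_fit_fun(config)

  R <- length(ns)
  sig <- conv <- integer(R)
  seeds <- replicate_seeds(config$master_seed, R)
  for (i in seq_len(R)) {
    set.seed(seeds[i])
    data <- if (is.null(config$fit_fun)) {
      generate_dataset(config$generation, ns[i])
    } else {
      NULL  # callback generates (or does not need) its own data
    }
    dec <- fit_fun(data, ns[i])
    sig[i] <- as.integer(dec$significant)
    conv[i] <- as.integer(dec$converged)
  }
  records <- data.frame(n = ns, significant = sig, converged = conv,
                        replicate_id = seq_len(R), seed = seeds)
  nonconv <- mean(records$converged == 0L)
  if (nonconv > 0.5) {
    mspe_abort(sprintf(
      "%.0f%% of replications failed to converge; the power fit would be unreliable",
      100 * nonconv), "mspe_config_error")
  }

  fits <- list()
  results <- list()
  for (m in config$methods) {
    fits[[m]] <- switch(m,
                        wald_sqrt = fit_wald_power_model(records, config$alpha),
                        naive = fit_naive(records, config$alpha_rho,
                                          config$alpha),
                        fit_power_model(records, m, config$alpha))
    results[[m]] <- tryCatch(
      required_n_lb(fits[[m]], config$rho, config$alpha_rho),
      mspe_error = function(e) e)
  }
  structure(list(records = records, fits = fits, results = results,
                 nonconvergence_rate = nonconv, config = config),
            class = "mspe_power_study")
}

#' @export
print.mspe_power_study <- function(x, ...) {
  cat(sprintf("Power study: R = %d records, non-convergence rate %.3f\n",
              nrow(x$records), x$nonconvergence_rate))
  for (m in names(x$results)) {
    r <- x$results[[m]]
    if (inherits(r, "mspe_samplesize")) {
      cat(sprintf("  %-12s N_alpha = %5d  N_lb = %5d\n", m, r$N_alpha, r$N_lb))
    } else {
      cat(sprintf("  %-12s inversion failed: %s\n", m, conditionMessage(r)))
    }
  }
  invisible(x)
}

#' Empirical reference power at a fixed sample size
#'
#' Estimates power at one sample size as the relative frequency of a
#' significant test among converged replications, with an exact
#' Clopper-Pearson confidence interval.
#'
#' @param config an [study_config()] (its allocation is ignored).
#' @param n the sample size.
#' @param R_ref number of replications (`>= 100`).
#' @param seed master seed for this reference run.
#' @param conf_level confidence level of the interval.
#' @return List with `p_hat`, `ci` (length 2), `n_converged`, `R_ref`.
#' @export
estimate_reference_power <- function(config, n, R_ref = 1000,
                                     seed = config$master_seed,
                                     conf_level = 0.95) {
  stopifnot(inherits(config, "mspe_study_config"))
  if (R_ref < 100) mspe_abort("R_ref must be >= 100", "mspe_config_error")
  fit_fun <- config$fit_fun %||% default_fit_fun(config)
  sig <- conv <- integer(R_ref)
  seeds <- replicate_seeds(seed, R_ref)
  for (i in seq_len(R_ref)) {
    set.seed(seeds[i])
    data <- if (is.null(config$fit_fun)) {
      generate_dataset(config$generation, n)
    } else {
      NULL
    }
    dec <- fit_fun(data, n)
    sig[i] <- dec$significant
    conv[i] <- dec$converged
  }
  k <- sum(conv == 1L)
  if (k == 0) mspe_abort("no replication converged", "mspe_config_error")
  x <- sum(sig[conv == 1L])
  bt <- stats::binom.test(x, k, conf.level = conf_level)
  list(p_hat = x / k, ci = as.numeric(bt$conf.int), n_converged = k,
       R_ref = R_ref)
}

#' Reference sample-size grids of the two study designs
#'
#' The linear-SEM design evaluates empirical reference power on 31 sample
#' sizes equally spaced from 50 to 650; the QISEM design on 22 sample sizes
#' equally spaced from 150 to 1200.
#'
#' @param study `"linear_sem"` (or `"study1"`) / `"qisem"` (or `"study2"`).
#' @return Integer vector of reference sample sizes.
#' @export
reference_grid <- function(study = c("linear_sem", "qisem",
                                     "study1", "study2")) {
  study <- match.arg(study)
  if (study %in% c("linear_sem", "study1")) {
    seq.int(50L, 650L, by = 20L)
  } else {
    seq.int(150L, 1200L, by = 50L)
  }
}

#' Evaluate power-modeling methods against a reference
#'
#' Computes the evaluation criteria over repeated studies: bias of the
#' estimated required sample size, bias of the predicted power at the true
#' required sample size, root mean squared error of the required sample size,
#' and the type I error proxy - the fraction of studies whose lower-bound
#' sample size falls below the true one.
#'
#' @param N_hat vector of point-estimate required sample sizes over studies.
#' @param N_lb vector of lower-bound required sample sizes over studies.
#' @param N_true true required sample size.
#' @param rho_hat optional vector of predicted power at `N_true` per study.
#' @param rho_ref optional reference power at `N_true`.
#' @return List of class `mspe_evaluation`: `bias_N`, `bias_rho`, `rmse_N`,
#'   `typeI`, `reps`.
#' @export
evaluate_methods <- function(N_hat, N_lb, N_true, rho_hat = NULL,
                             rho_ref = NULL) {
  stopifnot(length(N_hat) == length(N_lb), length(N_hat) >= 1)
  bias_rho <- if (!is.null(rho_hat) && !is.null(rho_ref)) {
    mean(rho_hat - rho_ref)
  } else {
    NA_real_
  }
  structure(list(bias_N = mean(N_hat - N_true),
                 bias_rho = bias_rho,
                 rmse_N = sqrt(mean((N_hat - N_true)^2)),
                 typeI = mean(N_lb < N_true),
                 reps = length(N_hat)),
            class = "mspe_evaluation")
}

#' @export
print.mspe_evaluation <- function(x, ...) {
  cat(sprintf(
    "Evaluation over %d studies: bias(N) = %.2f, RMSE(N) = %.2f, bias(rho) = %s, typeI = %.4f\n",
    x$reps, x$bias_N, x$rmse_N,
    if (is.na(x$bias_rho)) "NA" else sprintf("%.4f", x$bias_rho), x$typeI))
  invisible(x)
}

#' Idealized Bernoulli decision callback
#'
#' Returns a `fit_fun` for [study_config()] that draws significance
#' decisions directly from a known probit-on-sqrt(n) truth
#' `P(S = 1 | n) = Phi(beta0 + beta1 sqrt(n))`, bypassing any model fitting.
#' Used for calibration experiments where the generating power curve is the
#' oracle.
#'
#' @param beta0,beta1 true power-curve coefficients.
#' @return A function `(data, n) -> list(significant, converged)`.
#' @export
bernoulli_truth_fit_fun <- function(beta0, beta1) {
  force(beta0); force(beta1)
  function(data, n) {
    p <- stats::pnorm(beta0 + beta1 * sqrt(n))
    list(significant = as.integer(stats::runif(1) < p), converged = 1L)
  }
}
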