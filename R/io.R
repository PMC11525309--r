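# File interfaces: CSV significance logs, JSON fit/inversion results,
# and the combined machine/human report.

#' Read a significance-decision log
#'
#' Reads a CSV with header `n,significant,converged,replicate_id,seed`
#' (integer columns, UTF-8, no index column). Malformed rows are rejected
#' with their line numbers.
#'
#' @param path CSV file path.
#' @return A validated significance-record data frame.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) {
    mspe_abort(paste0("file not found: ", path), "mspe_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("n", "significant", "converged")
  if (!all(req %in% names(df))) {
    mspe_abort(paste0("missing required column(s): ",
                      paste(setdiff(req, names(df)), collapse = ", ")),
               "mspe_parse_error")
  }
  bad <- which(!(df$significant %in% c(0L, 1L)) |
                 !(df$converged %in% c(0L, 1L)) |
                 !is.finite(df$n) | df$n < 1)
  if (length(bad) > 0) {
    mspe_abort(paste0("malformed record(s) on line(s) ",
                      paste(bad + 1L, collapse = ", "),
                      " (header is line 1)"),
               "mspe_parse_error")
  }
  if (is.null(df$replicate_id)) df$replicate_id <- seq_len(nrow(df))
  if (is.null(df$seed)) df$seed <- NA_integer_
  validate_records(df[, c("n", "significant", "converged", "replicate_id",
                          "seed")])
}

#' Write a significance-decision log
#'
#' @param records significance-record data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  records <- validate_records(records)
  utils::write.csv(records[, c("n", "significant", "converged",
                               "replicate_id", "seed")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @keywords internal
#' @noRd
fit_to_list <- function(fit) {
  out <- list(method = fit$method, alpha = fit$alpha,
              n_records = fit$n_records,
              dropped_nonconverged = fit$dropped_nonconverged,
              converged = fit$converged)
  if (fit$method == "naive") {
    out$alpha_rho <- fit$alpha_rho
    out$naive_table <- fit$naive_table
  } else {
    out$beta0 <- fit$beta0
    out$beta1 <- fit$beta1
    out$vcov <- as.numeric(t(fit$vcov))  # row-major 2x2
  }
  out
}

#' Write a fitted power-curve model to JSON
#'
#' Serialises method, alpha, coefficients, the row-major 2x2 coefficient
#' covariance (or the naive grid table), and the record counts, at full
#' float precision.
#'
#' @param fit an `mspe_power_fit`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_power_fit <- function(fit, path) {
  stopifnot(inherits(fit, "mspe_power_fit"))
  jsonlite::write_json(fit_to_list(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted power-curve model from JSON
#'
#' @param path JSON path written by [write_power_fit()].
#' @return An `mspe_power_fit`.
#' @export
read_power_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- list(method = x$method, alpha = x$alpha,
              beta0 = x$beta0 %||% NULL, beta1 = x$beta1 %||% NULL,
              vcov = if (!is.null(x$vcov)) matrix(x$vcov, 2, 2, byrow = TRUE),
              naive_table = x$naive_table %||% NULL,
              alpha_rho = x$alpha_rho %||% NULL,
              loglik = NA_real_, n_records = x$n_records,
              dropped_nonconverged = x$dropped_nonconverged,
              converged = isTRUE(x$converged), iterations = NA_integer_)
  class(fit) <- "mspe_power_fit"
  fit
}

#' Write or read a SEM specification as JSON
#'
#' Each model matrix is serialised as a list of entries
#' `{matrix, row, col, free, value, label}` (free entries carry their start
#' value and label; fixed nonzero entries their fixed value), together with
#' the latent/indicator names and the focal parameter.
#'
#' @param spec an [sem_spec()].
#' @param path JSON file path.
#' @return `path` invisibly (write); an `mspe_sem_spec` (read).
#' @export
write_sem_spec <- function(spec, path) {
  stopifnot(inherits(spec, "mspe_sem_spec"))
  entries <- list()
  for (mt in c("lambda", "beta", "psi", "theta")) {
    v <- spec[[mt]]$value; f <- spec[[mt]]$free
    keep <- which(f | v != 0, arr.ind = TRUE)
    if (mt %in% c("psi", "theta")) {
      keep <- keep[keep[, 1] >= keep[, 2], , drop = FALSE]
    }
    for (k in seq_len(nrow(keep))) {
      r <- keep[k, 1]; cc <- keep[k, 2]
      lab <- spec$param_table$label[
        spec$param_table$matrix == mt & spec$param_table$row == r &
          spec$param_table$col == cc]
      entries[[length(entries) + 1L]] <- list(
        matrix = mt, row = r, col = cc, free = unname(f[r, cc]),
        value = unname(v[r, cc]),
        label = if (length(lab)) lab else NULL)
    }
  }
  jsonlite::write_json(
    list(latent_names = spec$latent_names,
         indicator_names = spec$indicator_names,
         focal_label = spec$focal_label, entries = entries),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sem_spec
#' @export
read_sem_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  lat <- unlist(x$latent_names); ind <- unlist(x$indicator_names)
  m <- length(lat); p <- length(ind)
  dims <- list(lambda = c(p, m), beta = c(m, m), psi = c(m, m),
               theta = c(p, p))
  mats <- lapply(dims, function(d) {
    list(value = matrix(0, d[1], d[2]), free = matrix(FALSE, d[1], d[2]))
  })
  for (e in x$entries) {
    r <- e$row; cc <- e$col
    mats[[e$matrix]]$value[r, cc] <- e$value
    mats[[e$matrix]]$free[r, cc] <- isTRUE(e$free)
    if (e$matrix %in% c("psi", "theta")) {
      mats[[e$matrix]]$value[cc, r] <- e$value
      mats[[e$matrix]]$free[cc, r] <- isTRUE(e$free)
    }
  }
  sem_spec(mats$lambda, mats$beta, mats$psi, mats$theta,
           latent_names = lat, indicator_names = ind,
           focal_label = x$focal_label)
}

#' Write a generated dataset with a provenance sidecar
#'
#' Writes the indicator table as headered CSV and a `<path>.meta.json`
#' sidecar recording the generation config, its hash, the seed, and the
#' number of cases, so any dataset on disk can be traced to (and regenerated
#' from) its configuration.
#'
#' @param data indicator data frame from [generate_dataset()].
#' @param path output CSV path.
#' @param config the [generation_config()] used.
#' @param seed the RNG seed used.
#' @return Character vector of the two paths, invisibly.
#' @export
write_dataset <- function(data, path, config, seed) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  cfg <- unclass(config)
  sidecar <- paste0(path, ".meta.json")
  jsonlite::write_json(
    list(config = cfg,
         config_hash = paste0("md5:", digest_config(cfg)),
         seed = seed, n = nrow(data)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(path, sidecar))
}

#' @keywords internal
#' @noRd
digest_config <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a combined analysis report
#'
#' Emits a machine-readable JSON report and a Markdown summary covering the
#' fitted power models (coefficients with standard errors and the
#' `beta0 + q_{1-alpha}` diagnostic), the required-sample-size inversions,
#' an optional method evaluation, and run diagnostics (record counts,
#' non-convergence rate).
#'
#' @param fits named list of `mspe_power_fit` objects.
#' @param inversions named list of `mspe_samplesize` objects (may be empty).
#' @param evaluation optional `mspe_evaluation`.
#' @param path output path without extension; `<path>.json` and `<path>.md`
#'   are written.
#' @param nonconvergence_rate optional rate to include in diagnostics.
#' @return Character vector of the two paths, invisibly.
#' @export
write_report <- function(fits, inversions = list(), evaluation = NULL,
                         path = "mspe-report", nonconvergence_rate = NULL) {
  stopifnot(length(fits) > 0)
  json_path <- paste0(path, ".json")
  md_path <- paste0(path, ".md")

  rep_fits <- lapply(fits, function(f) {
    out <- fit_to_list(f)
    if (f$method %in% c("probit_sqrt", "wald_sqrt") && !is.null(f$beta0)) {
      q <- if (f$method == "wald_sqrt") {
        stats::qnorm(1 - f$alpha / 2)
      } else {
        stats::qnorm(1 - f$alpha)
      }
      out$beta0_deviation_from_asymptote <- f$beta0 + q
    }
    out
  })
  rep_inv <- lapply(inversions, function(r) {
    list(method = r$method, rho = r$rho, N_alpha = r$N_alpha, N_lb = r$N_lb,
         rho_hat_lb = r$rho_hat_lb, alpha_rho = r$alpha_rho)
  })
  payload <- list(fits = rep_fits, inversions = rep_inv)
  if (!is.null(evaluation)) payload$evaluation <- unclass(evaluation)
  if (!is.null(nonconvergence_rate)) {
    payload$diagnostics <- list(nonconvergence_rate = nonconvergence_rate)
  }
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)

  lines <- c("# Power analysis report", "", "## Fitted power models", "")
  for (nm in names(fits)) {
    f <- fits[[nm]]
    if (f$method == "naive") {
      lines <- c(lines, sprintf("- **%s**: 4-point interpolation, grid (%s)",
                                nm, paste(f$naive_table$n, collapse = ", ")))
    } else {
      se <- sqrt(diag(f$vcov))
      lines <- c(lines, sprintf(
        "- **%s**: beta0 = %.4f (SE %.4f), beta1 = %.5f (SE %.5f), records = %d, dropped = %d",
        nm, f$beta0, se[1], f$beta1, se[2], f$n_records,
        f$dropped_nonconverged))
    }
  }
  if (length(inversions) > 0) {
    lines <- c(lines, "", "## Required sample sizes", "")
    for (nm in names(inversions)) {
      r <- inversions[[nm]]
      lines <- c(lines, sprintf(
        "- **%s**: rho = %.2f -> N = %d (lower-bound N = %d, crossing power %.4f)",
        nm, r$rho, r$N_alpha, r$N_lb, r$rho_hat_lb))
    }
  }
  if (!is.null(evaluation)) {
    lines <- c(lines, "", "## Method evaluation", "", sprintf(
      "- bias(N) = %.3f, RMSE(N) = %.3f, typeI = %.4f over %d studies",
      evaluation$bias_N, evaluation$rmse_N, evaluation$typeI,
      evaluation$reps))
  }
  if (!is.null(nonconvergence_rate)) {
    lines <- c(lines, "", sprintf("Non-convergence rate: %.4f",
                                  nonconvergence_rate))
  }
  writeLines(lines, md_path)
  invisible(c(json_path, md_path))
}
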