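#' Build a table of significance records
#'
#' A significance record stores the outcome of one simulated replication of a
#' power study: the sample size `n` at which data were generated, the binary
#' significance decision of the z-test, and whether the model fit that produced
#' the decision converged. Records with `converged = 0` carry no significance
#' information and are dropped (and counted) by every power-curve fit.
#'
#' @param n integer vector of sample sizes (all `>= 1`).
#' @param significant binary vector (0/1 or logical) of significance decisions.
#' @param converged binary vector (0/1 or logical); defaults to all converged.
#' @param replicate_id integer replicate identifiers.
#' @param seed optional integer seed provenance per replication.
#'
#' @return A `data.frame` with columns `n`, `significant`, `converged`,
#'   `replicate_id`, `seed`.
#' @examples
#' significance_records(n = c(100, 200), significant = c(0, 1))
#' @export
significance_records <- function(n, significant, converged = 1L,
                                 replicate_id = seq_along(n), seed = NA_integer_) {
  df <- data.frame(
    n = as.integer(n),
    significant = as.integer(significant),
    converged = as.integer(rep_len(converged, length(n))),
    replicate_id = as.integer(rep_len(replicate_id, length(n))),
    seed = as.integer(rep_len(seed, length(n)))
  )
  validate_records(df)
}

#' @keywords internal
#' @noRd
validate_records <- function(records) {
  req <- c("n", "significant", "converged")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0) {
    mspe_abort(paste0("records lack required column(s): ",
                      paste(missing_cols, collapse = ", ")),
               "mspe_parse_error")
  }
  bad <- which(!(records$significant %in% c(0L, 1L)) |
                 !(records$converged %in% c(0L, 1L)) |
                 records$n < 1 | !is.finite(records$n))
  if (length(bad) > 0) {
    mspe_abort(paste0("invalid record(s) at row(s): ",
                      paste(utils::head(bad, 10L), collapse = ", "),
                      " (need n >= 1, significant and converged in {0,1})"),
               "mspe_parse_error")
  }
  if (is.null(records$replicate_id)) records$replicate_id <- seq_len(nrow(records))
  if (is.null(records$seed)) records$seed <- NA_integer_
  records
}

#' @keywords internal
#' @noRd
converged_records <- function(records) {
  records <- validate_records(records)
  keep <- records$converged == 1L
  list(records = records[keep, , drop = FALSE], dropped = sum(!keep))
}
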