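#' Form double-mean-centered matched product indicators
#'
#' Implements the double-mean-centering construction for measuring a latent
#' interaction: each raw indicator in a pair is mean-centered, the pairwise
#' products are formed, and each product column is mean-centered again, so
#' every product indicator has exactly zero sample mean and no mean structure
#' is needed in the fitted model. Pairs must be matched: each raw indicator
#' appears in at most one pair.
#'
#' @param data data frame (or matrix) of indicator scores.
#' @param pairs list of length-2 character vectors naming the paired columns,
#'   e.g. `list(c("x1", "x4"), c("x2", "x5"), c("x3", "x6"))`.
#'
#' @return `data` with the product columns appended, named `"a.b"` for pair
#'   `(a, b)`.
#' @export
make_product_indicators <- function(data, pairs) {
  data <- as.data.frame(data)
  if (length(pairs) == 0) return(data)
  all_ind <- unlist(pairs)
  if (!all(all_ind %in% names(data))) {
    mspe_abort(paste0("unknown indicator(s): ",
                      paste(setdiff(all_ind, names(data)), collapse = ", ")),
               "mspe_spec_error")
  }
  if (anyDuplicated(all_ind)) {
    mspe_abort("matched product indicators require each indicator in at most one pair",
               "mspe_spec_error")
  }
  if (any(vapply(pairs, function(pr) pr[1] == pr[2], logical(1)))) {
    mspe_abort("a pair must reference two distinct indicators", "mspe_spec_error")
  }
  for (pr in pairs) {
    a <- data[[pr[1]]] - mean(data[[pr[1]]])
    b <- data[[pr[2]]] - mean(data[[pr[2]]])
    prod_col <- a * b
    data[[paste0(pr[1], ".", pr[2])]] <- prod_col - mean(prod_col)
  }
  data
}

#' Extend a SEM spec with an unconstrained product-indicator interaction
#'
#' Adds one latent interaction factor, measured by the product indicators of
#' the given matched pairs, to a base linear SEM: the first product
#' indicator's loading is fixed to 1 (marker), the remaining loadings are
#' free; the interaction factor gets a free variance, free covariances with
#' both interacting exogenous factors, free product-indicator residual
#' variances, and one free structural path to the dependent factor (the new
#' focal parameter). No nonlinear constraints are imposed - the
#' "unconstrained" variant - so the model is fitted with ordinary linear-SEM
#' ML machinery.
#'
#' @param base an [sem_spec()] containing the two interacting exogenous
#'   latents.
#' @param pairs matched indicator pairs, as in [make_product_indicators()].
#' @param interacting length-2 character vector of the interacting exogenous
#'   latent names.
#' @param outcome name of the endogenous latent receiving the interaction
#'   path.
#' @param interaction_name name for the new latent factor.
#' @param start_loading,start_path,start_var start values for the new free
#'   parameters.
#'
#' @return An `mspe_sem_spec` whose `focal_label` is the interaction path.
#' @export
build_upi_spec <- function(base, pairs, interacting = c("xi1", "xi2"),
                           outcome = "eta1",
                           interaction_name = paste(interacting, collapse = ":"),
                           start_loading = 1, start_path = 0.1,
                           start_var = 1.25) {
  stopifnot(inherits(base, "mspe_sem_spec"))
  if (length(pairs) == 0) return(base)
  if (!all(interacting %in% base$latent_names) ||
      !(outcome %in% base$latent_names)) {
    mspe_abort("interacting/outcome latents not found in base spec",
               "mspe_spec_error")
  }
  prod_names <- vapply(pairs, function(pr) paste0(pr[1], ".", pr[2]),
                       character(1))
  p0 <- nrow(base$lambda$value); m0 <- ncol(base$lambda$value)
  k <- length(prod_names)

  grow <- function(mat, nr, nc) {
    out <- matrix(if (is.logical(mat)) FALSE else 0, nr, nc)
    out[seq_len(nrow(mat)), seq_len(ncol(mat))] <- mat
    out
  }
  Lv <- grow(base$lambda$value, p0 + k, m0 + 1)
  Lf <- grow(base$lambda$free, p0 + k, m0 + 1)
  Lv[p0 + seq_len(k), m0 + 1] <- start_loading
  Lv[p0 + 1, m0 + 1] <- 1                      # marker fixed
  Lf[p0 + seq_len(k), m0 + 1] <- c(FALSE, rep(TRUE, k - 1))

  Bv <- grow(base$beta$value, m0 + 1, m0 + 1)
  Bf <- grow(base$beta$free, m0 + 1, m0 + 1)
  io <- match(outcome, base$latent_names)
  Bv[io, m0 + 1] <- start_path
  Bf[io, m0 + 1] <- TRUE

  Pv <- grow(base$psi$value, m0 + 1, m0 + 1)
  Pf <- grow(base$psi$free, m0 + 1, m0 + 1)
  Pv[m0 + 1, m0 + 1] <- start_var
  Pf[m0 + 1, m0 + 1] <- TRUE
  for (nm in interacting) {
    i <- match(nm, base$latent_names)
    Pf[m0 + 1, i] <- Pf[i, m0 + 1] <- TRUE     # start value 0
  }

  Tv <- grow(base$theta$value, p0 + k, p0 + k)
  Tf <- grow(base$theta$free, p0 + k, p0 + k)
  diag(Tv)[p0 + seq_len(k)] <- 0.5
  diag(Tf)[p0 + seq_len(k)] <- TRUE

  sem_spec(list(value = Lv, free = Lf), list(value = Bv, free = Bf),
           list(value = Pv, free = Pf), list(value = Tv, free = Tf),
           latent_names = c(base$latent_names, interaction_name),
           indicator_names = c(base$indicator_names, prod_names),
           focal_label = paste0(outcome, "~", interaction_name))
}
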