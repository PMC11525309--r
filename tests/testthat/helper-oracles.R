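# shared oracles and fixture builders (all fixtures generated in code)

sample_skew <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3

sample_exkurt <- function(x) mean((x - mean(x))^4) / stats::sd(x)^4 - 3

# records drawn from a known probit-on-sqrt(n) truth over an integer range
probit_truth_records <- function(R, beta0, beta1, n_min = 51, n_max = 600,
                                 cycle = TRUE) {
  grid <- n_min:n_max
  n <- if (cycle) grid[((seq_len(R) - 1L) %% length(grid)) + 1L] else
    sample(grid, R, replace = TRUE)
  p <- pnorm(beta0 + beta1 * sqrt(n))
  significance_records(n, rbinom(R, 1, p))
}

# sample whose ML covariance equals Sigma exactly (whitened-normal trick):
# feeds a moment-matched dataset to the fitter
moment_matched_sample <- function(Sigma, n) {
  p <- ncol(Sigma)
  Z <- matrix(rnorm(n * p), n, p)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  W <- Z %*% solve(chol(crossprod(Z) / n))
  X <- W %*% chol(Sigma)
  colnames(X) <- colnames(Sigma)
  X
}

# generic bounded-optimization refit of the probit/logit likelihood,
# independent of the package's Newton fitter
refit_by_optim <- function(records, method) {
  rec <- records[records$converged == 1L, ]
  g <- if (grepl("_sqrt$", method)) sqrt(rec$n) else rec$n
  y <- rec$significant
  linkinv <- if (grepl("^probit", method)) pnorm else plogis
  negll <- function(b) {
    p <- pmin(pmax(linkinv(b[1] + b[2] * g), 1e-12), 1 - 1e-12)
    -sum(ifelse(y == 1, log(p), log1p(-p)))
  }
  sc <- c(1, 1 / max(g))
  o <- optim(c(-1, 1 / max(g)), negll, method = "L-BFGS-B",
             lower = c(-50, 0), upper = c(50, 5),
             control = list(maxit = 5000, factr = 1, parscale = sc))
  # polish with a Nelder-Mead pass started from the box solution
  optim(o$par, negll, method = "Nelder-Mead",
        control = list(maxit = 20000, reltol = 1e-14))$par
}
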