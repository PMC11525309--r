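# SEM engine: implied moments, ML fit, sandwich SEs, z-test, UPI machinery

test_that("implied moments follow the path-tracing rules", {
  spec <- study1_spec()
  Sig <- implied_moments(spec)
  # latent Cov(eta1, xi1) = g11 + g12*phi12 = .2 + .5*.5 = .45, visible in
  # the marker-indicator cross-covariance
  expect_equal(Sig["y1", "x1"], 0.45, tolerance = 1e-12)
  # marker variance = latent variance + residual
  expect_equal(Sig["x1", "x1"], 1 + 0.36, tolerance = 1e-12)
  # within-scale covariance = product of loadings
  expect_equal(Sig["x1", "x2"], 0.8, tolerance = 1e-12)
  expect_true(all(eigen(Sig, symmetric = TRUE)$values > 0))

  # all loadings and paths zero -> Sigma = Theta
  z <- study1_spec(loadings = c(0, 0, 0), gamma11 = 0, gamma12 = 0,
                   beta21 = 0, gamma21 = 0, gamma22 = 0, phi12 = 0,
                   zeta_var = c(1, 1))
  expect_equal(unname(implied_moments(z)), diag(0.36, 12), tolerance = 1e-12)
})

test_that("a singular structural system is rejected", {
  spec <- study1_spec()
  bad <- spec$beta
  bad$value[3, 3] <- 1  # eta1 regressed on itself
  expect_error(sem_spec(spec$lambda, bad, spec$psi, spec$theta,
                        spec$latent_names, spec$indicator_names),
               class = "mspe_spec_error")
})

test_that("population covariance is recovered exactly from moment-matched data", {
  spec <- study1_spec()
  Sig <- implied_moments(spec)
  set.seed(201)
  X <- moment_matched_sample(Sig, 300)
  fit <- fit_ml(X, spec)
  expect_true(fit$converged)
  expect_lt(fit$fmin, 1e-10)
  expect_lt(max(abs(fit$estimates - mspe:::spec_start_vector(spec))), 1e-6)
  expect_lt(fit$gradient_norm, 1e-6)
})

test_that("ML fit recovers generating parameters with calibrated SEs", {
  spec <- study1_spec()
  cfg <- study1_config()
  set.seed(202)
  dat <- generate_dataset(cfg, 10000)
  fit <- fit_ml(dat, spec, robust = TRUE)
  expect_true(fit$converged)
  g11 <- fit$estimates[["eta1~xi1"]]
  expect_lt(abs(g11 - 0.2) / fit$se_naive[["eta1~xi1"]], 3)
  # correctly specified normal data: sandwich ~ inverse information
  ratio <- fit$se_robust / fit$se_naive
  expect_lt(abs(ratio[["eta1~xi1"]] - 1), 0.1)
})

test_that("z-test follows the quantile rules and sign conventions", {
  fake <- structure(list(estimates = c("eta1~xi1" = 0.2),
                         se_naive = c("eta1~xi1" = 0.1),
                         se_robust = NULL, converged = TRUE,
                         spec = list(focal_label = "eta1~xi1")),
                    class = "mspe_sem_fit")
  zt <- z_test(fake, "eta1~xi1", "two_sided", alpha = 0.05)
  expect_equal(zt$z_value, 2, tolerance = 1e-12)
  expect_equal(zt$p_two_sided, 2 * pnorm(-2), tolerance = 1e-12)
  expect_equal(round(zt$p_two_sided, 4), 0.0455)
  expect_identical(zt$significant, 1L)
  # zero estimate never significant
  fake$estimates[1] <- 0
  expect_identical(z_test(fake, sided = "two_sided")$significant, 0L)
  # one-sided with positive hypothesis and z = -3: not significant
  fake$estimates[1] <- -0.3
  zt3 <- z_test(fake, sided = "one_sided", hypothesized_sign = 1)
  expect_identical(zt3$significant, 0L)
  # but significant if the hypothesized direction is negative
  zt4 <- z_test(fake, sided = "one_sided", hypothesized_sign = -1)
  expect_identical(zt4$significant, 1L)
  expect_error(z_test(fake, "not~there"), class = "mspe_lookup_error")
})

test_that("double-mean-centered product indicators have exactly zero mean", {
  set.seed(203)
  cfg <- study2_config()
  dat <- generate_dataset(cfg, 2000)
  pairs <- list(c("x1", "x4"), c("x2", "x5"), c("x3", "x6"))
  aug <- make_product_indicators(dat, pairs)
  expect_identical(ncol(aug), 15L)
  expect_lt(max(abs(colMeans(aug[, 13:15]))), 1e-12)
  # centered product of a centered normal is uncorrelated with its factors
  big <- as.data.frame(matrix(rnorm(2e5 * 2), ncol = 2))
  names(big) <- c("a", "b")
  big$b <- 0.5 * big$a + sqrt(0.75) * big$b
  aug2 <- make_product_indicators(big, list(c("a", "b")))
  expect_lt(abs(cov(aug2$a.b, big$a)), 0.02)
  # constant column in a pair -> constant-zero product
  cst <- data.frame(u = rep(2, 50), v = rnorm(50))
  expect_true(all(make_product_indicators(cst, list(c("u", "v")))$u.v == 0))
  # matching violations
  expect_error(make_product_indicators(dat, list(c("x1", "x4"),
                                                 c("x1", "x5"))),
               class = "mspe_spec_error")
  expect_error(make_product_indicators(dat, list(c("x1", "zzz"))),
               class = "mspe_spec_error")
})

test_that("the UPI construction adds exactly the unconstrained parameter set", {
  base <- study1_spec()
  pairs <- list(c("x1", "x4"), c("x2", "x5"), c("x3", "x6"))
  upi <- build_upi_spec(base, pairs)
  expect_identical(ncol(upi$lambda$value), 5L)
  expect_identical(nrow(upi$lambda$value), 15L)
  tb <- upi$param_table
  tb0 <- base$param_table
  new <- tb[!(tb$label %in% tb0$label), ]
  # 2 free loadings (marker fixed), 1 structural path, 1 variance,
  # 2 covariances with the interacting factors, 3 residual variances
  expect_identical(sum(new$matrix == "lambda"), 2L)
  expect_identical(sum(new$matrix == "beta"), 1L)
  expect_identical(sum(new$matrix == "psi" & new$row == new$col), 1L)
  expect_identical(sum(new$matrix == "psi" & new$row != new$col), 2L)
  expect_identical(sum(new$matrix == "theta"), 3L)
  expect_identical(nrow(new), 9L)
  # marker loading fixed to 1
  expect_equal(upi$lambda$value[13, 5], 1)
  expect_false(upi$lambda$free[13, 5])
  expect_identical(upi$focal_label, "eta1~xi1:xi2")
  # zero pairs: spec unchanged
  expect_identical(build_upi_spec(base, list()), base)
})

test_that("UPI fit recovers the latent interaction effect at large n", {
  cfg <- study2_config()
  pairs <- list(c("x1", "x4"), c("x2", "x5"), c("x3", "x6"))
  spec2 <- build_upi_spec(study1_spec(), pairs)
  set.seed(204)
  dat <- generate_dataset(cfg, 20000)
  aug <- make_product_indicators(dat, pairs)
  fit <- fit_ml(aug, spec2, robust = TRUE)
  expect_true(fit$converged)
  g13 <- fit$estimates[[spec2$focal_label]]
  expect_lt(abs(g13 - 0.1), 4 * fit$se_robust[[spec2$focal_label]])
  expect_lt(abs(g13 - 0.1), 0.05)
})
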