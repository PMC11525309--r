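# synthetic-data generators: Fleishman/Vale-Maurelli, standardization, seeds

test_that("Fleishman coefficients satisfy the moment identities", {
  # normal target: identity transform
  expect_equal(unname(fleishman_coefficients(0, 0)), c(0, 1, 0, 0),
               tolerance = 1e-10)
  # study targets: plug-in moments reproduce the targets to 1e-8
  for (tg in list(c(1.7, 7.2), c(0.7, 2.5), c(2, 7))) {
    cf <- fleishman_coefficients(tg[1], tg[2])
    m <- mspe:::fleishman_moments(cf["b"], cf["c"], cf["d"])
    expect_lt(abs(m[["var"]] - 1), 1e-8)
    expect_lt(abs(m[["skew"]] - tg[1]), 1e-8)
    expect_lt(abs(m[["exkurt"]] - tg[2]), 1e-8)
    expect_equal(cf[["a"]], -cf[["c"]])
  }
  # below the universal moment bound: rejected outright
  expect_error(fleishman_coefficients(3, 1), class = "mspe_feasibility_error")
})

test_that("targets outside the Fleishman region error unless boundary opt-in", {
  # (2.3, 6.5) passes the universal bound but no Fleishman cubic attains it
  # (minimum representable excess kurtosis at skewness 2.3 is ~7.26): the
  # moment-identity oracle itself proves infeasibility, so the strict path
  # must refuse rather than silently miss the target
  expect_error(fleishman_coefficients(2.3, 6.5),
               class = "mspe_feasibility_error")
  expect_warning(cf <- fleishman_coefficients(2.3, 6.5,
                                              allow_boundary = TRUE),
                 "boundary")
  ach <- attr(cf, "achieved")
  expect_lt(abs(ach[["var"]] - 1), 0.01)
  # the boundary solution lands near, not at, the target
  expect_lt(abs(ach[["skew"]] - 2.3), 0.2)
})

test_that("intermediate correlations reduce correctly and match targets", {
  cfs <- list(fleishman_coefficients(1.7, 7.2),
              fleishman_coefficients(0.7, 2.5))
  # identity target stays the identity
  expect_equal(vm_intermediate_correlation(diag(2), cfs), diag(2))
  # all-normal coefficients: cubic reduces to r = rho
  norm2 <- list(fleishman_coefficients(0, 0), fleishman_coefficients(0, 0))
  tg <- matrix(c(1, .37, .37, 1), 2, 2)
  expect_equal(vm_intermediate_correlation(tg, norm2), tg, tolerance = 1e-10)
  # non-normal pair: intermediate correlation differs from the target but
  # the generated data reproduce the target
  R <- vm_intermediate_correlation(matrix(c(1, .5, .5, 1), 2, 2), cfs)
  expect_gt(R[1, 2], 0.5)  # polynomial attenuates, so rho must exceed r
  set.seed(301)
  X <- generate_vale_maurelli(1e6, matrix(c(1, .5, .5, 1), 2, 2),
                              skew = c(1.7, 0.7), exkurt = c(7.2, 2.5))
  expect_lt(abs(cor(X)[1, 2] - 0.5), 0.005)
  expect_error(vm_intermediate_correlation(matrix(c(1, 1.2, 1.2, 1), 2, 2),
                                           cfs),
               class = "mspe_feasibility_error")
})

test_that("VM-generated variables hit their moment targets at n = 1e6", {
  set.seed(302)
  X <- generate_vale_maurelli(1e6, matrix(c(1, .5, .5, 1), 2, 2),
                              skew = c(1.7, 1.7), exkurt = c(7.2, 7.2))
  for (j in 1:2) {
    expect_lt(abs(sample_skew(X[, j]) - 1.7), 0.05)
    expect_lt(abs(sample_exkurt(X[, j]) - 7.2), 0.3)
    expect_lt(abs(sd(X[, j]) - 1), 0.01)
    expect_lt(abs(mean(X[, j])), 0.01)
  }
})

test_that("standardizing residual variances match the variance algebra", {
  # interaction condition: Var(zeta1) = 1 - (.04 + .25 + .10 + .0125)
  cfg2 <- study2_config()
  vz <- solve_standardizing_residuals(cfg2)
  expect_equal(vz[["zeta1"]], 0.5975, tolerance = 1e-12)
  # all coefficients zero: full unit residual
  cfg0 <- generation_config("linear_sem", gamma11 = 0, gamma12 = 0,
                            beta21 = 0, gamma21 = 0, gamma22 = 0)
  expect_equal(unname(solve_standardizing_residuals(cfg0)), c(1, 1))
  # orthogonal predictors, no interaction
  cfgo <- generation_config("linear_sem", phi12 = 0)
  expect_equal(solve_standardizing_residuals(cfgo)[["zeta1"]],
               1 - 0.04 - 0.25, tolerance = 1e-12)
  # infeasible standardization
  expect_error(solve_standardizing_residuals(
    generation_config("linear_sem", gamma11 = 0.9, gamma12 = 0.9)),
    class = "mspe_config_error")
})

test_that("latent variables are standardized and the product term has the Isserlis variance", {
  cfg2 <- study2_config()
  set.seed(303)
  lat <- generate_latents(cfg2, 1e6)
  expect_lt(max(abs(apply(lat, 2, var) - 1)), 0.01)
  # Var(xi1 xi2) = 1 + phi12^2 = 1.25 for centered bivariate normal
  # (tolerance ~4 Monte-Carlo SDs: the squared product has heavy tails)
  expect_lt(abs(var(lat[, "xi1"] * lat[, "xi2"]) - 1.25), 0.03)
})

test_that("generation is seed-deterministic and the QISEM nests the linear SEM", {
  cfg <- study2_config()
  d1 <- generate_dataset(cfg, 500, seed = 42)
  d2 <- generate_dataset(cfg, 500, seed = 42)
  expect_identical(d1, d2)
  # gamma13 = 0 reduces the QISEM draws to the linear-SEM draws exactly
  cfg_null <- generation_config("qisem", gamma13 = 0)
  cfg_lin <- generation_config("linear_sem")
  expect_identical(generate_dataset(cfg_null, 300, seed = 7),
                   generate_dataset(cfg_lin, 300, seed = 7))
})

test_that("indicators follow the measurement model", {
  cfg <- study1_config()
  set.seed(304)
  lat <- generate_latents(cfg, 1e5)
  X <- generate_indicators(lat)
  # Cov(x1, x2) = lambda1 * lambda2 * Var(xi1) = .8
  expect_lt(abs(cov(X$x1, X$x2) - 0.8), 0.02)
  expect_lt(abs(var(X$x1) - 1.36), 0.03)
  # zero residual variance: exact loading multiples
  X0 <- generate_indicators(lat[1:100, ], theta_residuals = 0)
  expect_equal(X0$x2, 0.8 * lat[1:100, "xi1"], tolerance = 1e-12)
  expect_error(generate_indicators(lat[1:10, ], loadings = c(1, .8)),
               class = "mspe_spec_error")
  expect_error(generate_indicators(lat[1:10, ], theta_residuals = -1),
               class = "mspe_spec_error")
})

test_that("manifest-placement non-normality yields non-normal indicators", {
  cfg <- generation_config(
    "linear_sem",
    distribution = list(type = "vale_maurelli",
                        skew = rep(c(0.7, 1.2), 6),
                        exkurt = rep(c(2.5, 4), 6),
                        placement = "manifest"))
  set.seed(305)
  X <- generate_dataset(cfg, 2e5)
  expect_lt(abs(sample_skew(X$x1) - 0.7), 0.1)
  expect_lt(abs(sample_skew(X$x2) - 1.2), 0.1)
  # covariance structure still matches the model-implied one
  expect_lt(abs(cov(X$x1, X$x2) - 0.8), 0.03)
  # manifest placement is defined for the linear SEM only
  expect_error(generation_config(
    "qisem",
    distribution = list(type = "vale_maurelli", skew = rep(1, 12),
                        exkurt = rep(3, 12), placement = "manifest")),
    class = "mspe_config_error")
})
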