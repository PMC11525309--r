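# power-curve models: analytic power, fits, prediction bands, inversion

test_that("analytic power matches the normal-CDF evaluation", {
  # null effect: power equals the test level, one- and two-sided
  expect_equal(analytic_power(effect_spec(0, 1), 100), 0.05, tolerance = 1e-10)
  expect_equal(analytic_power(effect_spec(0, 3, "two_sided"), 77), 0.05,
               tolerance = 1e-10)
  # direct evaluation at theta0 = .2, psi = 2, n = 400
  expect_equal(analytic_power(effect_spec(0.2, 2), 400),
               pnorm(-qnorm(0.95) + 0.1 * 20), tolerance = 1e-12)
  expect_equal(round(analytic_power(effect_spec(0.2, 2), 400), 4), 0.6388)
  # power increases in n and approaches 1
  pw <- analytic_power(effect_spec(0.3, 1.5, "two_sided"), c(10, 100, 1000))
  expect_true(all(diff(pw) > 0))
  expect_error(effect_spec(0.2, -1), class = "mspe_effect_error")
})

test_that("probit/logit fits recover their generating coefficients", {
  set.seed(101)
  rec <- probit_truth_records(50000, -1.6449, 0.12)
  fit <- fit_power_model(rec, "probit_sqrt", alpha = 0.05)
  expect_true(fit$converged)
  expect_lt(abs(fit$beta0 - (-1.6449)), 0.05)
  expect_lt(abs(fit$beta1 - 0.12), 0.005)
  # within 3 estimated standard errors of the truth
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$beta0 + 1.6449) / se[1], 3)
  expect_lt(abs(fit$beta1 - 0.12) / se[2], 3)

  # logit truth recovered by the logit fit
  set.seed(102)
  n <- rep(51:600, length.out = 30000)
  p <- plogis(-3 + 0.006 * n)
  recl <- significance_records(n, rbinom(30000, 1, p))
  fl <- fit_power_model(recl, "logit_n")
  expect_lt(abs(fl$beta0 - (-3)), 3 * sqrt(fl$vcov[1, 1]))
  expect_lt(abs(fl$beta1 - 0.006), 3 * sqrt(fl$vcov[2, 2]))
})

test_that("ML fit agrees with an independent bounded-optimization refit and glm", {
  set.seed(103)
  for (method in c("probit_sqrt", "logit_n")) {
    rec <- probit_truth_records(5000, -1.5, 0.1)
    fit <- fit_power_model(rec, method)
    ref <- refit_by_optim(rec, method)
    expect_lt(max(abs(c(fit$beta0, fit$beta1) - ref)), 1e-6)
    g <- if (grepl("_sqrt$", method)) sqrt(rec$n) else rec$n
    fam <- binomial(link = if (grepl("^probit", method)) "probit" else "logit")
    gl <- glm(rec$significant ~ g, family = fam,
              control = list(epsilon = 1e-12))
    expect_lt(max(abs(c(fit$beta0, fit$beta1) - coef(gl))), 1e-6)
  }
})

test_that("degenerate and separated decision logs raise typed errors", {
  rec0 <- significance_records(c(100, 200, 300), c(0, 0, 0))
  expect_error(fit_power_model(rec0, "probit_sqrt"),
               class = "mspe_separation_error")
  rec1 <- significance_records(c(100, 200, 300), c(1, 1, 1))
  expect_error(fit_power_model(rec1, "probit_sqrt"),
               class = "mspe_separation_error")
  # perfectly ordered outcomes
  recs <- significance_records(c(100, 150, 400, 500), c(0, 0, 1, 1))
  expect_error(fit_power_model(recs, "probit_sqrt"),
               class = "mspe_separation_error")
  expect_error(fit_wald_power_model(recs), class = "mspe_separation_error")
  # non-converged records are dropped and counted
  set.seed(104)
  rec <- probit_truth_records(2000, -1.6, 0.12)
  rec$converged[1:100] <- 0L
  fit <- fit_power_model(rec, "probit_sqrt")
  expect_equal(fit$dropped_nonconverged, 100)
  expect_equal(fit$n_records, 1900)
})

test_that("non-converged fits refuse prediction and inversion", {
  fake <- structure(list(method = "probit_sqrt", alpha = 0.05, beta0 = -1.6,
                         beta1 = 0.1, vcov = diag(2), naive_table = NULL,
                         converged = FALSE),
                    class = "mspe_power_fit")
  expect_error(predict_power(fake, 100), class = "mspe_fit_error")
  expect_error(required_n(fake, 0.8), class = "mspe_fit_error")
})

test_that("wald model recovers a two-sided truth and matches probit at high power", {
  set.seed(105)
  n <- rep(51:600, length.out = 50000)
  p <- pnorm(-1.95996 + 0.12 * sqrt(n)) + pnorm(-1.95996 - 0.12 * sqrt(n))
  rec <- significance_records(n, rbinom(50000, 1, p))
  fit <- fit_wald_power_model(rec, alpha = 0.05)
  expect_true(fit$converged)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$beta0 + 1.95996) / se[1], 3)
  expect_lt(abs(fit$beta1 - 0.12) / se[2], 3)

  # two-term mean function agrees with the one-sided probit curve once the
  # mirrored term vanishes (mu = beta1 sqrt(n) >= 8)
  n_hi <- (8.5 / fit$beta1)^2
  two_term <- pnorm(fit$beta0 + fit$beta1 * sqrt(n_hi)) +
    pnorm(fit$beta0 - fit$beta1 * sqrt(n_hi))
  one_sided <- pnorm(fit$beta0 + fit$beta1 * sqrt(n_hi))
  expect_lt(abs(two_term - one_sided), 1e-6)
})

test_that("a null two-sided truth yields flat power at the test level", {
  # beta1 = 0 at beta0 = -q_{.975}: mean function is alpha everywhere
  b0 <- qnorm(0.025)
  p <- pnorm(b0 + 0) + pnorm(b0 - 0)
  expect_equal(p, 0.05, tolerance = 1e-12)
  set.seed(106)
  n <- rep(seq(100, 900, by = 100), each = 400)
  rec <- significance_records(n, rbinom(length(n), 1, 0.05))
  fit <- fit_wald_power_model(rec)
  expect_true(fit$boundary || fit$beta1 < 0.02)
  pred <- pnorm(fit$beta0 + fit$beta1 * sqrt(c(100, 900))) +
    pnorm(fit$beta0 - fit$beta1 * sqrt(c(100, 900)))
  expect_lt(max(abs(pred - 0.05)), 0.02)
})

test_that("prediction bands behave at the degenerate and exact points", {
  fit <- structure(list(method = "probit_sqrt", alpha = 0.05,
                        beta0 = -2, beta1 = 0.1,
                        vcov = matrix(0, 2, 2), naive_table = NULL,
                        converged = TRUE),
                   class = "mspe_power_fit")
  # linear predictor 0 at n = 400 -> power exactly .5
  pr <- predict_power(fit, 400)
  expect_equal(pr$rho_hat, 0.5, tolerance = 1e-12)
  # zero covariance -> zero-width band
  expect_equal(pr$lb, pr$rho_hat)
  expect_equal(pr$ub, pr$rho_hat)
  # with a covariance, the band orders correctly and stays in [0, 1]
  fit$vcov <- matrix(c(0.04, -0.002, -0.002, 0.0002), 2, 2)
  pr2 <- predict_power(fit, c(10, 400, 3000), alpha_rho = 0.05)
  expect_true(all(pr2$lb <= pr2$rho_hat & pr2$rho_hat <= pr2$ub))
  expect_true(all(pr2$lb >= 0 & pr2$ub <= 1))
})

test_that("required_n reproduces the closed-form inversions", {
  fit <- structure(list(method = "probit_sqrt", alpha = 0.05,
                        beta0 = -1.644854, beta1 = 0.1,
                        vcov = matrix(0, 2, 2), naive_table = NULL,
                        converged = TRUE),
                   class = "mspe_power_fit")
  # independent arithmetic: ceil(((0.841621 + 1.644854)/0.1)^2) = 619
  expect_identical(required_n(fit, 0.80), 619L)
  # classical one-sample z-test sample size
  expect_identical(required_n(effect_spec(0.5, 1), 0.80), 25L)
  # exact-integer roundtrip: rho on the curve at integer m returns m
  for (m in c(100L, 250L, 619L)) {
    rho_m <- pnorm(-1.644854 + 0.1 * sqrt(m))
    expect_identical(required_n(fit, rho_m), m)
  }
  # cap and degenerate-slope errors
  expect_error(required_n(fit, 0.995), class = "mspe_cap_error")
  fit$beta1 <- -0.01
  expect_error(required_n(fit, 0.8), class = "mspe_inversion_error")
})

test_that("closed-form inversion agrees with bisection on random coefficients", {
  set.seed(107)
  for (i in 1:200) {
    b0 <- runif(1, -3, -1)
    b1 <- runif(1, 0.05, 0.3)
    rho <- runif(1, 0.3, 0.99)
    fit <- structure(list(method = "probit_sqrt", alpha = 0.05, beta0 = b0,
                          beta1 = b1, vcov = matrix(0, 2, 2),
                          naive_table = NULL, converged = TRUE),
                     class = "mspe_power_fit")
    closed <- required_n(fit, rho)
    bisect <- mspe:::bisect_smallest_n(function(n) pnorm(b0 + b1 * sqrt(n)),
                                       rho)
    expect_identical(closed, bisect)
  }
})

test_that("inversion is consistent with prediction across methods", {
  set.seed(108)
  rec <- probit_truth_records(20000, -1.96, 0.11)
  fits <- list(fit_power_model(rec, "probit_sqrt"),
               fit_power_model(rec, "logit_sqrt"),
               fit_power_model(rec, "probit_n"),
               fit_power_model(rec, "logit_n"),
               fit_wald_power_model(rec))
  for (fit in fits) {
    for (rho in c(0.5, 0.8, 0.95)) {
      N <- required_n(fit, rho)
      expect_gte(predict_power(fit, N)$rho_hat, rho - 1e-9)
      if (N > 1) expect_lt(predict_power(fit, N - 1)$rho_hat, rho)
    }
    # fitted curves with beta1 > 0 are strictly increasing in n
    pr <- predict_power(fit, seq(60, 2000, by = 97))$rho_hat
    expect_true(all(diff(pr) > 0))
  }
})

test_that("lower-bound N exceeds the point estimate and responds to vcov", {
  base <- structure(list(method = "probit_sqrt", alpha = 0.05,
                         beta0 = -1.6449, beta1 = 0.12,
                         vcov = matrix(c(4e-3, -2e-4, -2e-4, 2e-5), 2, 2),
                         naive_table = NULL, converged = TRUE),
                    class = "mspe_power_fit")
  res <- required_n_lb(base, 0.80, 0.05)
  expect_gte(res$N_lb, res$N_alpha)
  # zero-width band: the two coincide and the crossing power equals rho
  zero <- base; zero$vcov <- matrix(0, 2, 2)
  res0 <- required_n_lb(zero, 0.80)
  expect_identical(res0$N_lb, res0$N_alpha)
  expect_equal(res0$rho_hat_lb, 0.80, tolerance = 1e-5)
  # inflating the coefficient covariance widens the band: N_lb grows,
  # N_alpha cannot change
  wide <- base; wide$vcov <- 4 * base$vcov
  res4 <- required_n_lb(wide, 0.80)
  expect_identical(res4$N_alpha, res$N_alpha)
  expect_gt(res4$N_lb, res$N_lb)
})

test_that("naive four-point interpolation fits, predicts, and inverts", {
  # fixed grid with known per-point frequencies
  set.seed(109)
  n <- rep(c(100, 200, 300, 400), each = 500)
  p_true <- c(0.2, 0.5, 0.8, 0.95)[match(n, c(100, 200, 300, 400))]
  rec <- significance_records(n, rbinom(length(n), 1, p_true))
  fit <- fit_naive(rec, alpha_rho = 0.05)
  expect_equal(fit$naive_table$R_j, rep(500L, 4))
  # midpoint of a linear segment (using the realized frequencies)
  pr <- predict_power(fit, 150)
  expect_equal(pr$rho_hat,
               mean(fit$naive_table$p_hat[1:2]), tolerance = 1e-12)
  # all-significant point: interval clipped at 1
  recc <- significance_records(rep(c(100, 200, 300, 400), each = 100),
                               c(rbinom(300, 1, 0.5), rep(1, 100)))
  fitc <- fit_naive(recc)
  expect_equal(fitc$naive_table$ub[4], 1)
  expect_equal(fitc$naive_table$p_hat[4], 1)
  # grid and extrapolation errors
  expect_error(fit_naive(significance_records(c(100, 200, 300),
                                              c(0, 1, 1))),
               class = "mspe_grid_error")
  expect_error(predict_power(fit, 450), class = "mspe_extrapolation_error")
  # inversion: first crossing of the polyline, lower-bound crossing above it
  N <- required_n(fit, 0.7)
  expect_true(N >= 200 && N <= 300)
  res <- required_n_lb(fit, 0.7)
  expect_gte(res$N_lb, res$N_alpha)
  # target beyond the grid's reach
  expect_error(required_n(fit, 0.99), class = "mspe_not_achievable_error")
})
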