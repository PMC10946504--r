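test_that("design matrix encodes the segmented regressors", {
  X <- build_design(12, 7)
  expect_equal(dim(X), c(12L, 4L))
  expect_equal(X[1:6, "D"], rep(0, 6))
  expect_equal(X[1:6, "tD"], rep(0, 6))
  expect_equal(X[7, c("D", "tD")], c(D = 1, tD = 0))
  expect_equal(X[12, "tD"], c(tD = 5))
  expect_equal(qr(X)$rank, 4L)

  X100 <- build_design(100, 51)
  expect_equal(sum(X100[, "D"] == 0), 50L)  # equal pre/post split
  expect_equal(sum(X100[, "D"] == 1), 50L)

  expect_error(build_design(10, 9), "segments too short")
})

test_that("OLS recovers an exact segmented line and matches lm", {
  TI <- 25L
  tt <- 1:48
  y_exact <- 1 * (tt >= TI) + 0.1 * (tt - TI) * (tt >= TI)
  f <- fit_ols(as_its_series(y_exact, TI))
  expect_equal(unname(f$beta_hat), c(0, 0, 1, 0.1), tolerance = 1e-12)
  expect_identical(f$method_used, "OLS")
  expect_true(f$converged)
  expect_identical(f$rho_hat, 0)

  set.seed(101)
  s <- generate_its_series(its_params(beta2 = 1, beta3 = 0.1, rho = 0.3), 48)
  f <- fit_ols(s)
  d <- data.frame(y = s$y, t = s$t,
                  D = as.numeric(s$t >= s$interruption))
  d$tD <- (d$t - s$interruption) * d$D
  lmf <- lm(y ~ t + D + tD, data = d)
  expect_equal(unname(f$beta_hat), unname(coef(lmf)), tolerance = 1e-10)
  expect_equal(unname(f$se), unname(sqrt(diag(vcov(lmf)))),
               tolerance = 1e-10)
})

test_that("OLS level-change is unbiased under autocorrelation", {
  set.seed(111)
  b2 <- replicate(1000, {
    s <- generate_its_series(its_params(beta2 = 1, rho = 0.4), 48)
    fit_ols(s)$beta_hat[["beta2"]]
  })
  mcse <- sd(b2) / sqrt(length(b2))
  expect_lt(abs(mean(b2) - 1), 3 * mcse)
})

test_that("Prais-Winsten whitens the residuals", {
  set.seed(121)
  s <- generate_its_series(its_params(beta2 = 1, rho = 0.6), 1e4)
  f <- fit_pw(s)
  expect_true(f$converged)
  expect_equal(f$rho_hat, 0.6, tolerance = 0.03)
  # residuals of the transformed model have (near-)zero lag-1 autocorrelation
  X <- build_design(s$n_obs, s$interruption)
  es <- metaits:::pw_transform(s$y, f$rho_hat) -
    metaits:::pw_transform(X, f$rho_hat) %*% f$beta_hat
  r1 <- sum(es[-1] * es[-length(es)]) / sum(es^2)
  expect_lt(abs(r1), 0.02)
})

test_that("Prais-Winsten converges across short-series batches", {
  set.seed(131)
  for (T in c(12, 48)) {
    conv <- replicate(100, {
      s <- generate_its_series(its_params(beta2 = 1, rho = 0.4), T)
      fit_pw(s)$converged
    })
    expect_true(all(conv))
  }
})

test_that("the whitening transform at rho = 0 is the identity", {
  x <- matrix(rnorm(20), 5)
  expect_identical(metaits:::pw_transform(x, 0), x)
})

test_that("REML matches an independent AR(1) GLS implementation", {
  skip_if_not_installed("nlme")
  set.seed(141)
  for (i in 1:5) {
    s <- generate_its_series(its_params(beta2 = 1, beta3 = 0.1, rho = 0.4),
                             48)
    f <- fit_reml(s)
    d <- data.frame(y = s$y, t = s$t,
                    D = as.numeric(s$t >= s$interruption))
    d$tD <- (d$t - s$interruption) * d$D
    g <- nlme::gls(y ~ t + D + tD, data = d,
                   correlation = nlme::corAR1(form = ~t), method = "REML")
    expect_equal(unname(f$beta_hat), unname(coef(g)), tolerance = 1e-5)
    expect_equal(unname(f$se), unname(sqrt(diag(vcov(g)))),
                 tolerance = 1e-4)
    expect_equal(f$rho_hat,
                 as.numeric(coef(g$modelStruct$corStruct,
                                 unconstrained = FALSE)),
                 tolerance = 1e-4)
  }
})

test_that("REML profile optimum agrees with an exhaustive grid search", {
  set.seed(151)
  for (i in 1:20) {
    rho <- runif(1, 0, 0.7)
    s <- generate_its_series(its_params(beta2 = 1, rho = rho), 48)
    f <- fit_reml(s)
    if (!f$converged) next  # boundary solutions have no interior optimum
    expect_near(f$rho_hat, grid_reml_rho(s), 1e-3)
  }
})

test_that("REML non-convergence concentrates in short series", {
  set.seed(161)
  rate <- vapply(c(12, 48, 100), function(T) {
    mean(replicate(150, {
      s <- generate_its_series(its_params(beta2 = 1, beta3 = 0.1,
                                          rho = 0.4), T)
      !fit_reml(s)$converged
    }))
  }, numeric(1))
  expect_gt(rate[1], rate[2])           # 12 clearly worst
  expect_gte(rate[2], rate[3])          # 48 no better than 100
  expect_gt(rate[1], 0.05)
})

test_that("the cascade falls back in preference order", {
  set.seed(171)
  s <- generate_its_series(its_params(rho = 0.2), 48)

  f <- fit_cascade(s)
  expect_identical(f$method_used, "REML")

  # fault injection: a REML fitter that never converges
  failing_reml <- function(series) {
    f <- fit_reml(series)
    f$converged <- FALSE
    f
  }
  f2 <- fit_cascade(s, fitters = list(REML = failing_reml, PW = fit_pw,
                                      OLS = fit_ols))
  expect_identical(f2$method_used, "PW")

  f3 <- fit_cascade(s, order = "OLS")
  expect_identical(f3$method_used, "OLS")
  expect_equal(f3$beta_hat, fit_ols(s)$beta_hat)
})

test_that("all fitters are location-equivariant", {
  set.seed(181)
  s <- generate_its_series(its_params(beta2 = 1, rho = 0.4), 48)
  shifted <- as_its_series(s$y + 10, s$interruption)
  for (fitter in list(fit_ols, fit_pw, fit_reml)) {
    a <- fitter(s)
    b <- fitter(shifted)
    expect_equal(b$beta_hat[["beta0"]], a$beta_hat[["beta0"]] + 10,
                 tolerance = 1e-6)
    expect_equal(b$beta_hat[-1], a$beta_hat[-1], tolerance = 1e-6)
  }
})

test_that("OLS model SE understates the sampling SD under autocorrelation, REML does not", {
  set.seed(191)
  n <- 400
  ols_b2 <- reml_b2 <- ols_se <- reml_se <- numeric(n)
  for (i in 1:n) {
    s <- generate_its_series(its_params(beta2 = 1, rho = 0.6), 100)
    fo <- fit_ols(s)
    fr <- fit_cascade(s)
    ols_b2[i] <- fo$beta_hat[["beta2"]]; ols_se[i] <- fo$se[["beta2"]]
    reml_b2[i] <- fr$beta_hat[["beta2"]]; reml_se[i] <- fr$se[["beta2"]]
  }
  expect_lt(sqrt(mean(ols_se^2)) / sd(ols_b2), 0.85)
  expect_gt(sqrt(mean(reml_se^2)) / sd(reml_b2), 0.9)
})
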