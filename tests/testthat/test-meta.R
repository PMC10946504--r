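test_that("meta_input validates its contract", {
  expect_error(meta_input(1, se = 1), "at least 2")
  expect_error(meta_input(c(1, 2), se = c(1, 0)), "positive")
  expect_error(meta_input(c(1, 2)), "exactly one")
  expect_error(meta_input(c(1, 2), se = c(1, 1), variances = c(1, 1)),
               "exactly one")
})

test_that("fixed-effect pooling matches hand-computed weighted means", {
  sym <- fixed_effect_pool(meta_input(c(1, 1), se = c(1, 1)))
  expect_equal(sym$pooled, 1)
  expect_equal(sym$se_pooled, 1 / sqrt(2))

  tri <- fixed_effect_pool(meta_input(c(0, 2, 4), se = c(1, 1, 1)))
  expect_equal(tri$pooled, 2)
  expect_equal(tri$se_pooled, 1 / sqrt(3))
})

test_that("DerSimonian-Laird estimator matches direct evaluation", {
  # Q = 8, denominator 3 - 3/3 = 2, tau2 = (8 - 2)/2 = 3
  res <- dl_tau2(meta_input(c(0, 2, 4), se = c(1, 1, 1)))
  expect_equal(res$Q, 8)
  expect_equal(res$tau2, 3)

  # zero dispersion: Q = 0, truncation active
  z <- dl_tau2(meta_input(c(1, 1, 1), se = c(1, 2, 3)))
  expect_identical(z$tau2, 0)

  # under-dispersion truncates to exactly zero
  u <- dl_tau2(meta_input(c(1, 1.01, 0.99), se = c(1, 1, 1)))
  expect_identical(u$tau2, 0)
})

test_that("REML tau2 fixed point matches grid search and metafor", {
  inp <- toy_meta_input()
  res <- reml_tau2(inp)
  expect_true(res$converged)
  expect_equal(res$tau2, grid_reml_tau2(inp$yi, inp$vi), tolerance = 1e-4)

  skip_if_not_installed("metafor")
  mf <- metafor::rma(yi = inp$yi, vi = inp$vi, method = "REML",
                     control = list(tau2.min = 0))
  expect_equal(res$tau2, mf$tau2, tolerance = 1e-5)

  # zero dispersion truncates to zero
  expect_identical(reml_tau2(meta_input(c(1, 1, 1), se = c(1, 1, 1)))$tau2, 0)
})

test_that("random-effects pooling reduces to fixed at tau2 = 0", {
  inp <- toy_meta_input()
  re <- random_effects_pool(inp, 0)
  fe <- fixed_effect_pool(inp)
  expect_equal(re$pooled, fe$pooled)
  expect_equal(sqrt(re$variance), fe$se_pooled)

  hand <- random_effects_pool(meta_input(c(0, 2), se = c(1, 1)), tau2 = 1)
  expect_equal(hand$pooled, 1)
  expect_equal(hand$variance, 1)
})

test_that("Wald-type interval uses normal quantiles", {
  ci <- wt_ci(0, 1, 0.05)
  expect_equal(ci$ci_low, qnorm(0.025))
  expect_equal(ci$ci_high, qnorm(0.975))

  p <- wt_ci(1, 0.25, 0.05)$p_value
  expect_equal(p, 2 * (1 - pnorm(2)), tolerance = 1e-12)
})

test_that("HKSJ interval matches hand evaluation and degenerates at zero dispersion", {
  inp <- meta_input(c(0, 1, 2), se = c(1, 1, 1))
  ci <- hksj_ci(inp, tau2 = 0)
  # q = sum((y - 1)^2)/2 = 1, variance = q/sum(w) = 1/3
  expect_equal(ci$se, 1 / sqrt(3))
  expect_equal(ci$df, 2)
  expect_equal(ci$ci_high, 1 + qt(0.975, 2) / sqrt(3))
  expect_equal(ci$ci_low, 1 - qt(0.975, 2) / sqrt(3))

  degen <- hksj_ci(meta_input(c(1, 1, 1), se = c(1, 1, 1)), tau2 = 0)
  expect_equal(degen$ci_low, 1)
  expect_equal(degen$ci_high, 1)
})

test_that("meta_analyse combinations agree with an independent implementation", {
  skip_if_not_installed("metafor")
  inp <- toy_meta_input()

  fe <- meta_analyse(inp, model = "fixed")
  mf_fe <- metafor::rma(yi = inp$yi, vi = inp$vi, method = "FE")
  expect_equal(fe$pooled, as.numeric(coef(mf_fe)), tolerance = 1e-8)
  expect_equal(fe$se_pooled, mf_fe$se, tolerance = 1e-8)

  dlwt <- meta_analyse(inp, tau2_method = "DL", ci_method = "WT")
  mf_dl <- metafor::rma(yi = inp$yi, vi = inp$vi, method = "DL")
  expect_equal(dlwt$pooled, as.numeric(coef(mf_dl)), tolerance = 1e-8)
  expect_equal(dlwt$tau2, mf_dl$tau2, tolerance = 1e-8)
  expect_equal(c(dlwt$ci_low, dlwt$ci_high), c(mf_dl$ci.lb, mf_dl$ci.ub),
               tolerance = 1e-8)

  dlhk <- meta_analyse(inp, tau2_method = "DL", ci_method = "HKSJ")
  mf_hk <- metafor::rma(yi = inp$yi, vi = inp$vi, method = "DL",
                        test = "knha")
  expect_equal(c(dlhk$ci_low, dlhk$ci_high), c(mf_hk$ci.lb, mf_hk$ci.ub),
               tolerance = 1e-8)
  expect_equal(dlhk$p_value, mf_hk$pval, tolerance = 1e-8)

  rewt <- meta_analyse(inp, tau2_method = "REML", ci_method = "WT")
  mf_re <- metafor::rma(yi = inp$yi, vi = inp$vi, method = "REML")
  expect_equal(rewt$pooled, as.numeric(coef(mf_re)), tolerance = 1e-5)
  expect_equal(rewt$tau2, mf_re$tau2, tolerance = 1e-5)

  rehk <- meta_analyse(inp, tau2_method = "REML", ci_method = "HKSJ")
  mf_rh <- metafor::rma(yi = inp$yi, vi = inp$vi, method = "REML",
                        test = "knha")
  expect_equal(c(rehk$ci_low, rehk$ci_high), c(mf_rh$ci.lb, mf_rh$ci.ub),
               tolerance = 1e-4)
})

test_that("results are invariant to study order and equivariant to scale", {
  set.seed(201)
  for (i in 1:5) {
    k <- sample(3:8, 1)
    yi <- rnorm(k)
    sei <- runif(k, 0.1, 0.5)
    inp <- meta_input(yi, se = sei)
    perm <- sample(k)
    inp_p <- meta_input(yi[perm], se = sei[perm])
    c_scale <- runif(1, 0.5, 3)
    inp_s <- meta_input(c_scale * yi, se = c_scale * sei)
    for (m in seq_len(nrow(meta_method_grid()))) {
      mm <- meta_method_grid()[m, ]
      args <- list(model = mm$model,
                   tau2_method = if (mm$model == "fixed") "DL"
                                 else mm$tau2_method,
                   ci_method = mm$ci_method)
      a <- do.call(meta_analyse, c(list(inp), args))
      b <- do.call(meta_analyse, c(list(inp_p), args))
      d <- do.call(meta_analyse, c(list(inp_s), args))
      expect_equal(a$pooled, b$pooled, tolerance = 1e-10)
      expect_equal(a$tau2, b$tau2, tolerance = 1e-10)
      expect_equal(c(a$ci_low, a$ci_high), c(b$ci_low, b$ci_high),
                   tolerance = 1e-10)
      expect_equal(d$pooled, c_scale * a$pooled, tolerance = 1e-6)
      expect_equal(d$se_pooled, c_scale * a$se_pooled, tolerance = 1e-6)
      expect_equal(d$tau2, c_scale^2 * a$tau2, tolerance = 1e-6)
    }
  }
})

test_that("random-effects pooled variance is non-decreasing in tau2", {
  inp <- toy_meta_input()
  v <- vapply(seq(0, 2, by = 0.1),
              function(t2) random_effects_pool(inp, t2)$variance, numeric(1))
  expect_true(all(diff(v) >= 0))
})

test_that("fixed model rejects invalid combinations and zero tau2 collapses to fixed", {
  inp <- toy_meta_input()
  expect_error(meta_analyse(inp, model = "fixed", ci_method = "HKSJ"),
               "Wald-type")
  # a DL fit whose tau2 truncates to zero is numerically the fixed fit
  inp0 <- meta_input(c(1, 1.01, 0.99), se = c(1, 1, 1))
  dl <- meta_analyse(inp0, tau2_method = "DL", ci_method = "WT")
  fe <- meta_analyse(inp0, model = "fixed")
  expect_identical(dl$tau2, 0)
  expect_equal(dl$pooled, fe$pooled)
  expect_equal(dl$se_pooled, fe$se_pooled)
  expect_equal(c(dl$ci_low, dl$ci_high), c(fe$ci_low, fe$ci_high))
})
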