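# Shared fixtures for the test suite. Everything is generated in code;
# nothing is read from disk except the packaged example estimates.

# A small but heterogeneous meta-analysis input used by several oracles.
toy_meta_input <- function() {
  meta_input(c(0.2, 0.8, -0.1, 0.5, 1.1),
             se = c(0.25, 0.30, 0.20, 0.40, 0.35))
}

# Restricted log-likelihood of the standard random-effects meta-analysis
# model as a function of tau2, for grid-search oracles (independent of the
# iterative estimator under test).
meta_restricted_ll <- function(tau2, yi, vi) {
  w <- 1 / (vi + tau2)
  mu <- sum(w * yi) / sum(w)
  -0.5 * (sum(log(vi + tau2)) + log(sum(w)) + sum(w * (yi - mu)^2))
}

# Grid-search REML tau2 oracle (exhaustive over [0, upper] at `step`).
grid_reml_tau2 <- function(yi, vi, upper = 2, step = 1e-5) {
  grid <- seq(0, upper, by = step)
  ll <- vapply(grid, meta_restricted_ll, numeric(1), yi = yi, vi = vi)
  grid[which.max(ll)]
}

# Exhaustive grid-search oracle for the AR(1) REML autocorrelation: coarse
# scan over the whole range, then a fine scan around the coarse optimum.
grid_reml_rho <- function(series, coarse = 0.005, fine = 1e-4) {
  X <- build_design(series$n_obs, series$interruption)
  obj <- function(r) metaits:::reml_profile_neg2ll(r, series$y, X)
  g1 <- seq(-0.998, 0.998, by = coarse)
  v1 <- vapply(g1, obj, numeric(1))
  r0 <- g1[which.min(v1)]
  g2 <- seq(max(-0.999, r0 - 2 * coarse), min(0.999, r0 + 2 * coarse),
            by = fine)
  v2 <- vapply(g2, obj, numeric(1))
  g2[which.min(v2)]
}

# Absolute-deviation expectation: the published-value tolerances are stated
# in outcome units, not relative terms.
expect_near <- function(object, expected, tol) {
  act <- testthat::quasi_label(rlang::enquo(object))
  testthat::expect(
    abs(act$val - expected) <= tol,
    sprintf("%s (%.5f) differs from %.5f by more than %g",
            act$lab, act$val, expected, tol)
  )
  invisible(act$val)
}
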