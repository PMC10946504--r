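#' Segmented-regression design matrix
#'
#' Builds the `T x 4` design matrix of the segmented linear model: an
#' intercept, the time index `t`, the post-interruption indicator
#' `D = 1(t >= TI)` and the post-interruption trend term `(t - TI) * D`.
#'
#' @param n_obs Series length.
#' @param interruption Index `TI` of the first post-interruption point.
#' @return A numeric matrix with columns `intercept`, `t`, `D`, `tD`.
#' @export
#' @examples
#' build_design(12, 7)
build_design <- function(n_obs, interruption) {
  check_segments(as.integer(n_obs), as.integer(interruption))
  tt <- seq_len(n_obs)
  D <- as.numeric(tt >= interruption)
  X <- cbind(intercept = 1, t = tt, D = D, tD = (tt - interruption) * D)
  X
}

coef_names <- c("beta0", "beta1", "beta2", "beta3")

new_its_fit <- function(beta_hat, se, rho_hat, sigma2_hat, method_used,
                        converged, n_iter) {
  names(beta_hat) <- coef_names
  names(se) <- coef_names
  structure(
    list(beta_hat = beta_hat, se = se, rho_hat = rho_hat,
         sigma2_hat = sigma2_hat, method_used = method_used,
         converged = converged, n_iter = n_iter),
    class = "its_fit"
  )
}

#' @export
print.its_fit <- function(x, ...) {
  cat(sprintf("Segmented regression fit (%s%s)\n", x$method_used,
              if (x$converged) "" else ", NOT converged"))
  out <- cbind(estimate = x$beta_hat, se = x$se)
  print(round(out, 4))
  cat(sprintf("rho_hat = %.4f, sigma2_hat = %.4f\n", x$rho_hat, x$sigma2_hat))
  invisible(x)
}

# Prais-Winsten whitening of a vector (or each column of a matrix): the first
# row is scaled by sqrt(1 - rho^2), subsequent rows are quasi-differenced.
# Applied to stationary-AR(1) data this renders the errors i.i.d. with the
# innovation variance.
pw_transform <- function(x, rho) {
  if (is.matrix(x)) {
    n <- nrow(x)
    rbind(sqrt(1 - rho^2) * x[1L, , drop = FALSE],
          x[-1L, , drop = FALSE] - rho * x[-n, , drop = FALSE])
  } else {
    n <- length(x)
    c(sqrt(1 - rho^2) * x[1L], x[-1L] - rho * x[-n])
  }
}

# Lag-1 moment estimator of residual autocorrelation.
lag1_autocor <- function(e) {
  sum(e[-1L] * e[-length(e)]) / sum(e^2)
}

#' Ordinary least squares fit of the segmented regression
#'
#' Classical OLS point estimates and standard errors (residual variance with
#' denominator `T - 4`). Ignores autocorrelation: `rho_hat` is 0 by
#' construction and the fit always converges.
#'
#' @param series An `its_series` object.
#' @return An object of class `its_fit` with elements `beta_hat`, `se`,
#'   `rho_hat`, `sigma2_hat`, `method_used`, `converged`, `n_iter`.
#' @export
#' @examples
#' set.seed(1)
#' fit_ols(generate_its_series(its_params(beta2 = 1, rho = 0.4), 48))
fit_ols <- function(series) {
  stopifnot(inherits(series, "its_series"))
  X <- build_design(series$n_obs, series$interruption)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("singular design matrix", call. = FALSE)
  beta <- qr.coef(qr_x, series$y)
  res <- series$y - X %*% beta
  df <- series$n_obs - ncol(X)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * diag(XtXinv))
  new_its_fit(as.numeric(beta), se, rho_hat = 0, sigma2_hat = sigma2,
              method_used = "OLS", converged = TRUE, n_iter = 0L)
}

#' Prais-Winsten fit of the segmented regression
#'
#' Iterative generalised least squares for AR(1) errors: fit by OLS, estimate
#' the lag-1 residual autocorrelation, whiten outcome and design with the
#' Prais-Winsten transform (first observation retained with a
#' `sqrt(1 - rho^2)` scaling), refit, and repeat until the autocorrelation
#' estimate stabilises. Standard errors come from the transformed
#' (whitened) regression.
#'
#' @param series An `its_series` object.
#' @param tol Convergence tolerance on successive rho estimates.
#' @param max_iter Iteration cap; reaching it flags `converged = FALSE`.
#' @return An `its_fit` object with `method_used = "PW"`.
#' @export
fit_pw <- function(series, tol = 1e-6, max_iter = 100L) {
  stopifnot(inherits(series, "its_series"))
  X <- build_design(series$n_obs, series$interruption)
  y <- series$y
  n <- series$n_obs
  p <- ncol(X)

  beta <- qr.coef(qr(X), y)
  rho <- lag1_autocor(as.numeric(y - X %*% beta))
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (abs(rho) >= 1) rho <- sign(rho) * 0.999
    Xs <- pw_transform(X, rho)
    ys <- pw_transform(y, rho)
    qr_s <- qr(Xs)
    beta <- qr.coef(qr_s, ys)
    rho_new <- lag1_autocor(as.numeric(y - X %*% beta))
    if (abs(rho_new) >= 1) rho_new <- sign(rho_new) * 0.999
    if (abs(rho_new - rho) < tol) {
      rho <- rho_new
      converged <- TRUE
      break
    }
    rho <- rho_new
    if (iter >= max_iter) break
  }
  # final whitened fit at the converged rho
  Xs <- pw_transform(X, rho)
  ys <- pw_transform(y, rho)
  qr_s <- qr(Xs)
  beta <- qr.coef(qr_s, ys)
  res_s <- ys - Xs %*% beta
  sigma2 <- sum(res_s^2) / (n - p)
  se <- sqrt(sigma2 * diag(chol2inv(qr.R(qr_s))))
  new_its_fit(as.numeric(beta), se, rho_hat = rho, sigma2_hat = sigma2,
              method_used = "PW", converged = converged, n_iter = iter)
}

# Minus twice the restricted log-likelihood of the AR(1) segmented
# regression, profiled over beta and the innovation variance, up to an
# additive constant. Uses the Prais-Winsten whitening, under which the
# stationary AR(1) covariance has log-determinant -log(1 - rho^2) relative
# to sigma^2 I.
reml_profile_neg2ll <- function(rho, y, X) {
  n <- length(y)
  p <- ncol(X)
  Xs <- pw_transform(X, rho)
  ys <- pw_transform(y, rho)
  qr_s <- qr(Xs)
  if (qr_s$rank < p) return(Inf)
  beta <- qr.coef(qr_s, ys)
  rss <- sum((ys - Xs %*% beta)^2)
  sigma2 <- rss / (n - p)
  ldet_xtx <- 2 * sum(log(abs(diag(qr.R(qr_s)))))
  (n - p) * log(sigma2) - log1p(-rho^2) + ldet_xtx
}

#' REML fit of the segmented regression with AR(1) errors
#'
#' Maximises the restricted log-likelihood of the linear model with
#' stationary AR(1) error correlation. The likelihood is profiled over the
#' autocorrelation: at each candidate `rho` the GLS coefficients and
#' innovation variance have closed forms via the Prais-Winsten whitening,
#' leaving a one-dimensional optimisation over `rho` in (-0.999, 0.999).
#' Standard errors are the GLS standard errors at the REML estimates.
#'
#' A fit is flagged non-converged when the optimiser lands on the imposed
#' `rho` boundary or the objective is non-finite — the situations in which
#' the cascade ([fit_cascade()]) falls back to Prais-Winsten.
#'
#' @param series An `its_series` object.
#' @param rho_bound Box constraint for `|rho|` (default 0.999).
#' @param boundary_tol Distance from the bound treated as a boundary
#'   solution.
#' @return An `its_fit` object with `method_used = "REML"`.
#' @export
fit_reml <- function(series, rho_bound = 0.999, boundary_tol = 1e-4) {
  stopifnot(inherits(series, "its_series"))
  X <- build_design(series$n_obs, series$interruption)
  y <- series$y
  n <- series$n_obs
  p <- ncol(X)

  # coarse scan first: the profile can be multimodal for short series, and
  # a plain golden-section search over the whole range may settle into a
  # local minimum
  grid <- unique(c(-rho_bound, seq(-rho_bound, rho_bound, by = 0.05),
                   rho_bound))
  vals <- vapply(grid, function(r) reml_profile_neg2ll(r, y, X), numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(reml_profile_neg2ll, c(lo, hi), y = y, X = X,
                         tol = 1e-8)
  rho <- opt$minimum
  # a coarse endpoint can beat the interior optimum when the minimum sits
  # at the boundary
  if (vals[i] < opt$objective) {
    rho <- grid[i]
    opt$objective <- vals[i]
  }
  converged <- is.finite(opt$objective) &&
    abs(rho) < rho_bound - boundary_tol

  Xs <- pw_transform(X, rho)
  ys <- pw_transform(y, rho)
  qr_s <- qr(Xs)
  beta <- qr.coef(qr_s, ys)
  rss <- sum((ys - Xs %*% beta)^2)
  sigma2 <- rss / (n - p)
  se <- sqrt(sigma2 * diag(chol2inv(qr.R(qr_s))))
  new_its_fit(as.numeric(beta), se, rho_hat = rho, sigma2_hat = sigma2,
              method_used = "REML", converged = converged,
              n_iter = NA_integer_)
}

#' Fit a series with a method-preference cascade
#'
#' Tries each method in order and returns the first converged fit; the study
#' analysis arm of the simulation uses REML, falling back to Prais-Winsten
#' and finally OLS (which cannot fail on an estimable design).
#'
#' @param series An `its_series` object.
#' @param order Character vector, a non-empty subsequence of
#'   `c("REML", "PW", "OLS")` in preference order.
#' @param fitters Named list of fitting functions, one per method;
#'   overridable for fault-injection in tests.
#' @return An `its_fit`; `method_used` records which method succeeded. If no
#'   method in `order` converges the last attempt is returned as-is.
#' @export
#' @examples
#' set.seed(1)
#' s <- generate_its_series(its_params(rho = 0.4), 12)
#' fit_cascade(s)$method_used
fit_cascade <- function(series, order = c("REML", "PW", "OLS"),
                        fitters = list(REML = fit_reml, PW = fit_pw,
                                       OLS = fit_ols)) {
  order <- match.arg(order, c("REML", "PW", "OLS"), several.ok = TRUE)
  if (length(order) == 0L) stop("'order' must be non-empty", call. = FALSE)
  fit <- NULL
  for (m in order) {
    fit <- fitters[[m]](series)
    if (isTRUE(fit$converged)) return(fit)
  }
  fit
}
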