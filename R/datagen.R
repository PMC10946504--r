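#' True generating parameters of a segmented-regression ITS model
#'
#' Bundles the parameters of the interrupted time series (ITS) data model
#' \deqn{Y_t = \beta_0 + \beta_1 t + \beta_2 D_t + \beta_3 (t - T_I) D_t + e_t,}
#' where \eqn{D_t = 1} for \eqn{t \ge T_I} and the errors follow a stationary
#' AR(1) process \eqn{e_t = \rho e_{t-1} + w_t} with standard-normal white
#' noise \eqn{w_t}.
#'
#' @param beta0 Pre-interruption level (intercept), in outcome units.
#' @param beta1 Pre-interruption slope, outcome units per time step.
#' @param beta2 Immediate level-change at the interruption, outcome units.
#' @param beta3 Change in slope after the interruption, outcome units per
#'   time step.
#' @param rho Lag-1 autocorrelation of the errors; must lie in (-1, 1).
#' @param sigma_w White-noise standard deviation (fixed at 1 in the
#'   simulation design, but adjustable).
#'
#' @return An object of class `its_params`.
#' @export
#' @examples
#' its_params(beta2 = 1, beta3 = 0.1, rho = 0.4)
its_params <- function(beta0 = 0, beta1 = 0, beta2 = 0, beta3 = 0,
                       rho = 0, sigma_w = 1) {
  stopifnot(is.numeric(rho), length(rho) == 1L, is.finite(rho))
  if (rho <= -1 || rho >= 1)
    stop("'rho' must lie strictly inside (-1, 1)", call. = FALSE)
  if (!is.numeric(sigma_w) || sigma_w <= 0)
    stop("'sigma_w' must be positive", call. = FALSE)
  structure(
    list(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
         rho = rho, sigma_w = sigma_w),
    class = "its_params"
  )
}

#' Specify one simulation scenario
#'
#' A scenario is one cell of the factorial simulation design: the ITS
#' characteristics (series length, interruption point, interruption effects,
#' autocorrelation) crossed with the meta-analysis characteristics (number
#' of studies, between-study variances of the two interruption effects).
#'
#' @param n_obs Series length `T` (total number of time points). The study
#'   grid uses 12, 48 and 100; any length leaving at least 4 points on each
#'   side of the interruption is accepted.
#' @param interruption Time index `TI` of the first post-interruption point.
#'   Defaults to `n_obs / 2 + 1`, which puts exactly half of the points
#'   before and half after the interruption.
#' @param beta2,beta3 True mean level-change and slope-change.
#' @param rho Either a single number in (-1, 1) (autocorrelation fixed and
#'   shared by every study in the meta-analysis) or the string `"variable"`,
#'   in which case each study draws its own autocorrelation from
#'   Normal(`rho_mean`, `rho_sd`^2), resampled until it lies inside (-1, 1).
#' @param K Number of ITS studies per meta-analysis (at least 2).
#' @param tau2_level Between-study variance of the level-change (\eqn{\tau_2^2}).
#' @param tau2_slope Between-study variance of the slope-change (\eqn{\tau_3^2}).
#' @param n_reps Number of replicate meta-analyses for this scenario.
#' @param seed Base seed for the scenario's random streams.
#' @param rho_mean,rho_sd Mean and SD of the variable-autocorrelation
#'   distribution (defaults 0.4 and 0.15, the study's design values).
#'
#' @return An object of class `scenario_spec`.
#' @export
#' @examples
#' scenario_spec(n_obs = 48, beta2 = 1, beta3 = 0.1, rho = 0.2, K = 3,
#'               tau2_level = 0, tau2_slope = 0)
scenario_spec <- function(n_obs, interruption = NULL, beta2 = 0, beta3 = 0,
                          rho = 0, K = 3, tau2_level = 0, tau2_slope = 0,
                          n_reps = 1000, seed = 1L,
                          rho_mean = 0.4, rho_sd = 0.15) {
  if (is.null(interruption)) interruption <- floor(n_obs / 2) + 1L
  check_segments(n_obs, interruption)
  if (K < 2) stop("'K' must be at least 2", call. = FALSE)
  if (tau2_level < 0 || tau2_slope < 0)
    stop("between-study variances must be non-negative", call. = FALSE)
  if (identical(rho, "variable")) {
    rho_mode <- "variable"
    rho_value <- NA_real_
  } else {
    stopifnot(is.numeric(rho), length(rho) == 1L)
    if (rho <= -1 || rho >= 1)
      stop("'rho' must lie strictly inside (-1, 1)", call. = FALSE)
    rho_mode <- "fixed"
    rho_value <- rho
  }
  structure(
    list(n_obs = as.integer(n_obs), interruption = as.integer(interruption),
         beta2 = beta2, beta3 = beta3,
         rho_mode = rho_mode, rho_value = rho_value,
         rho_mean = rho_mean, rho_sd = rho_sd,
         K = as.integer(K), tau2_level = tau2_level, tau2_slope = tau2_slope,
         n_reps = as.integer(n_reps), seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

# Both segments need >= 4 points so the 4 regression coefficients are estimable
# from either side of the interruption.
check_segments <- function(n_obs, interruption) {
  if (interruption <= 1L || interruption > n_obs)
    stop("'interruption' must satisfy 1 < TI <= T", call. = FALSE)
  n_pre <- interruption - 1L
  n_post <- n_obs - interruption + 1L
  if (n_pre < 4L || n_post < 4L)
    stop(sprintf(
      "segments too short for estimation: %d pre and %d post points (need >= 4 each)",
      n_pre, n_post), call. = FALSE)
  invisible(TRUE)
}

#' Draw a study-level autocorrelation value
#'
#' In fixed mode returns the scenario's constant. In variable mode draws from
#' Normal(`rho_mean`, `rho_sd`^2) and redraws until the value lies strictly
#' inside (-1, 1) (rejection sampling of the out-of-range tail).
#'
#' @param spec A [scenario_spec()].
#' @param rnorm_fun Normal sampler, `function(n, mean, sd)`; replaceable for
#'   testing the rejection rule with a rigged stream.
#'
#' @return A single autocorrelation value in (-1, 1).
#' @export
draw_autocorrelation <- function(spec, rnorm_fun = stats::rnorm) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$rho_mode == "fixed") return(spec$rho_value)
  repeat {
    r <- rnorm_fun(1L, spec$rho_mean, spec$rho_sd)
    if (r > -1 && r < 1) return(r)
  }
}

#' Generate one interrupted time series
#'
#' Simulates a series from the segmented linear model with stationary AR(1)
#' errors. The first error is drawn from the stationary distribution
#' Normal(0, \eqn{\sigma_w^2 / (1 - \rho^2)}), so no burn-in is needed and
#' short series carry no start-up transient.
#'
#' @param truth An [its_params()] object.
#' @param n_obs Series length `T`.
#' @param interruption Interruption index `TI` (first post-interruption
#'   point); defaults to `n_obs / 2 + 1`.
#'
#' @return An object of class `its_series`: a list with elements `t`, `y`,
#'   `n_obs`, `interruption` and `truth`.
#' @export
#' @examples
#' set.seed(1)
#' s <- generate_its_series(its_params(beta2 = 1, rho = 0.4), n_obs = 48)
#' head(cbind(t = s$t, y = s$y))
generate_its_series <- function(truth, n_obs, interruption = NULL) {
  stopifnot(inherits(truth, "its_params"))
  if (is.null(interruption)) interruption <- floor(n_obs / 2) + 1L
  n_obs <- as.integer(n_obs)
  interruption <- as.integer(interruption)
  check_segments(n_obs, interruption)

  rho <- truth$rho
  e1 <- stats::rnorm(1L, 0, truth$sigma_w / sqrt(1 - rho^2))
  if (n_obs > 1L) {
    w <- stats::rnorm(n_obs - 1L, 0, truth$sigma_w)
    e <- c(e1, as.numeric(stats::filter(w, rho, method = "recursive",
                                        init = e1)))
  } else {
    e <- e1
  }
  tt <- seq_len(n_obs)
  D <- as.numeric(tt >= interruption)
  y <- truth$beta0 + truth$beta1 * tt + truth$beta2 * D +
    truth$beta3 * (tt - interruption) * D + e
  structure(
    list(t = tt, y = y, n_obs = n_obs, interruption = interruption,
         truth = truth),
    class = "its_series"
  )
}

#' Construct an ITS series object from observed data
#'
#' Wraps user-supplied data (no generating truth attached) so it can be
#' passed to the fitting functions.
#'
#' @param y Outcome vector, one value per time point.
#' @param interruption Index of the first post-interruption time point.
#' @param t Optional time index; defaults to `1:length(y)`.
#' @return An `its_series` object.
#' @export
as_its_series <- function(y, interruption, t = seq_along(y)) {
  n_obs <- length(y)
  stopifnot(length(t) == n_obs, !anyNA(y))
  check_segments(n_obs, as.integer(interruption))
  structure(
    list(t = as.numeric(t), y = as.numeric(y), n_obs = as.integer(n_obs),
         interruption = as.integer(interruption), truth = NULL),
    class = "its_series"
  )
}

#' Generate one replicate meta-analysis sample
#'
#' Draws `K` study-specific true interruption effects
#' \eqn{\beta_{2k} = \beta_2 + \delta_{2k}}, \eqn{\delta_{2k} \sim
#' N(0, \tau_2^2)} (and likewise for the slope-change with \eqn{\tau_3^2}),
#' assigns each study an autocorrelation (one shared constant in fixed mode;
#' an independent draw per study in variable mode), and generates each
#' study's series.
#'
#' @param spec A [scenario_spec()].
#' @return An object of class `meta_sample`: list with `series` (list of `K`
#'   [its_series][generate_its_series()] objects), `true_level_effects`,
#'   `true_slope_effects`, `rho` (length `K`) and `spec`.
#' @export
#' @examples
#' set.seed(7)
#' ms <- generate_meta_sample(scenario_spec(n_obs = 12, beta2 = 1, K = 3))
#' ms$true_level_effects
generate_meta_sample <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  K <- spec$K
  lev <- spec$beta2 + stats::rnorm(K, 0, sqrt(spec$tau2_level))
  slp <- spec$beta3 + stats::rnorm(K, 0, sqrt(spec$tau2_slope))
  if (spec$rho_mode == "fixed") {
    rho <- rep(spec$rho_value, K)
  } else {
    rho <- vapply(seq_len(K), function(i) draw_autocorrelation(spec),
                  numeric(1))
  }
  series <- vector("list", K)
  for (k in seq_len(K)) {
    truth <- its_params(beta0 = 0, beta1 = 0, beta2 = lev[k], beta3 = slp[k],
                        rho = rho[k])
    series[[k]] <- generate_its_series(truth, spec$n_obs, spec$interruption)
  }
  structure(
    list(series = series, true_level_effects = lev, true_slope_effects = slp,
         rho = rho, spec = spec),
    class = "meta_sample"
  )
}

#' Export a meta-analysis sample as a tidy data frame
#'
#' @param sample A [generate_meta_sample()] result.
#' @return A data frame with columns `study`, `t`, `y`.
#' @export
meta_sample_to_df <- function(sample) {
  stopifnot(inherits(sample, "meta_sample"))
  do.call(rbind, lapply(seq_along(sample$series), function(k) {
    s <- sample$series[[k]]
    data.frame(study = k, t = s$t, y = s$y)
  }))
}

#' @export
print.its_series <- function(x, ...) {
  cat(sprintf("Interrupted time series: %d points, interruption at t = %d\n",
              x$n_obs, x$interruption))
  if (!is.null(x$truth))
    cat(sprintf("  truth: beta2 = %g, beta3 = %g, rho = %g\n",
                x$truth$beta2, x$truth$beta3, x$truth$rho))
  invisible(x)
}
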