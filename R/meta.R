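#' Bundle study-level estimates for two-stage meta-analysis
#'
#' @param estimates Numeric vector of `K >= 2` study effect estimates
#'   (e.g. level-changes or slope-changes).
#' @param se Study standard errors; supply either `se` or `variances`.
#' @param variances Within-study variances; mutually exclusive with `se`.
#' @param label Optional effect label (`"level"` or `"slope"`), carried
#'   through to results.
#' @return An object of class `meta_input` with elements `yi` (estimates),
#'   `vi` (variances), `k` and `label`.
#' @export
#' @examples
#' meta_input(c(0, 2, 4), se = c(1, 1, 1))
meta_input <- function(estimates, se = NULL, variances = NULL,
                       label = NA_character_) {
  if (is.null(variances) == is.null(se))
    stop("supply exactly one of 'se' or 'variances'", call. = FALSE)
  vi <- if (is.null(variances)) se^2 else variances
  yi <- as.numeric(estimates)
  if (length(yi) < 2L) stop("need at least 2 studies", call. = FALSE)
  if (length(vi) != length(yi))
    stop("'estimates' and 'se'/'variances' lengths differ", call. = FALSE)
  if (anyNA(yi) || anyNA(vi) || any(!is.finite(vi)) || any(vi <= 0))
    stop("within-study variances must be positive and finite", call. = FALSE)
  structure(list(yi = yi, vi = as.numeric(vi), k = length(yi), label = label),
            class = "meta_input")
}

#' Fixed-effect (common-effect) inverse-variance pooling
#'
#' Pools with weights \eqn{W_k = 1/\sigma_k^2}; the pooled variance is
#' \eqn{1/\sum W_k}. The confidence interval is Wald-type (normal quantile).
#'
#' @param input A [meta_input()].
#' @param alpha Two-sided significance level (default 0.05).
#' @return A `meta_result` (see [meta_analyse()]).
#' @export
fixed_effect_pool <- function(input, alpha = 0.05) {
  stopifnot(inherits(input, "meta_input"))
  w <- 1 / input$vi
  pooled <- sum(w * input$yi) / sum(w)
  v <- 1 / sum(w)
  ci <- wt_ci(pooled, v, alpha)
  new_meta_result(model = "fixed", tau2_method = "none", ci_method = "WT",
                  pooled = pooled, se_pooled = sqrt(v),
                  ci_low = ci$ci_low, ci_high = ci$ci_high,
                  p_value = ci$p_value, alpha = alpha, tau2 = 0,
                  Q = cochran_q(input), df = NA_real_, converged = TRUE,
                  k = input$k, label = input$label)
}

cochran_q <- function(input) {
  w <- 1 / input$vi
  mu_fe <- sum(w * input$yi) / sum(w)
  sum((input$yi - mu_fe)^2 / input$vi)
}

#' DerSimonian-Laird between-study variance estimator
#'
#' Moment estimator derived from Cochran's Q (computed about the
#' fixed-effect pooled estimate, with fixed-effect weights), truncated at
#' zero:
#' \deqn{\hat\tau^2 = \max\left(0, \frac{Q - (K - 1)}
#'   {\sum W_k - \sum W_k^2 / \sum W_k}\right).}
#'
#' @param input A [meta_input()].
#' @return List with `tau2` and `Q`.
#' @export
#' @examples
#' dl_tau2(meta_input(c(0, 2, 4), se = c(1, 1, 1)))  # Q = 8, tau2 = 3
dl_tau2 <- function(input) {
  stopifnot(inherits(input, "meta_input"))
  w <- 1 / input$vi
  Q <- cochran_q(input)
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (input$k - 1)) / denom)
  list(tau2 = tau2, Q = Q)
}

#' REML between-study variance estimator
#'
#' Iterative restricted-maximum-likelihood estimator. With random-effects
#' weights \eqn{W_k = 1/(\sigma_k^2 + \tau^2)} and pooled mean
#' \eqn{\hat\mu = \sum W_k y_k / \sum W_k}, the update is
#' \deqn{\hat\tau^2 \leftarrow \max\left(0,
#'   \frac{\sum W_k^2 \{(y_k - \hat\mu)^2 - \sigma_k^2\}}{\sum W_k^2}
#'   + \frac{1}{\sum W_k}\right),}
#' iterated to a fixed point. The starting value is the maximum-likelihood
#' estimate of \eqn{\tau^2} (itself initialised at the DerSimonian-Laird
#' value and iterated a bounded number of times).
#'
#' @param input A [meta_input()].
#' @param tol Convergence tolerance on successive tau-squared values.
#' @param max_iter Iteration cap; reaching it flags `converged = FALSE`.
#' @return List with `tau2`, `converged` and `n_iter`.
#' @export
reml_tau2 <- function(input, tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(input, "meta_input"))
  yi <- input$yi
  vi <- input$vi

  # ML initialiser: same iteration without the 1/sum(W) REML correction
  tau2 <- dl_tau2(input)$tau2
  for (i in seq_len(20L)) {
    w <- 1 / (vi + tau2)
    mu <- sum(w * yi) / sum(w)
    tau2_new <- max(0, sum(w^2 * ((yi - mu)^2 - vi)) / sum(w^2))
    if (abs(tau2_new - tau2) < tol) {
      tau2 <- tau2_new
      break
    }
    tau2 <- tau2_new
  }

  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    w <- 1 / (vi + tau2)
    mu <- sum(w * yi) / sum(w)
    tau2_new <- max(0, sum(w^2 * ((yi - mu)^2 - vi)) / sum(w^2) + 1 / sum(w))
    if (abs(tau2_new - tau2) < tol) {
      tau2 <- tau2_new
      converged <- TRUE
      break
    }
    tau2 <- tau2_new
    if (iter >= max_iter) break
  }
  list(tau2 = tau2, converged = converged, n_iter = iter)
}

#' Random-effects inverse-variance pooling at a given tau-squared
#'
#' Pools with weights \eqn{W_k = 1/(\sigma_k^2 + \tau^2)}; the base pooled
#' variance is \eqn{1/\sum W_k}.
#'
#' @param input A [meta_input()].
#' @param tau2 Between-study variance (>= 0).
#' @return List with `pooled`, `variance` and `weights`.
#' @export
random_effects_pool <- function(input, tau2) {
  stopifnot(inherits(input, "meta_input"), tau2 >= 0)
  w <- 1 / (input$vi + tau2)
  list(pooled = sum(w * input$yi) / sum(w), variance = 1 / sum(w),
       weights = w)
}

#' Wald-type confidence interval
#'
#' Normal-quantile symmetric interval
#' \eqn{\hat\mu \pm z_{1-\alpha/2} \sqrt{\mathrm{Var}(\hat\mu)}}, with the
#' two-sided p-value from the standard normal.
#'
#' @param pooled Pooled estimate.
#' @param variance Its variance (> 0).
#' @param alpha Two-sided significance level.
#' @return List with `ci_low`, `ci_high`, `se`, `p_value`.
#' @export
wt_ci <- function(pooled, variance, alpha = 0.05) {
  stopifnot(variance > 0)
  se <- sqrt(variance)
  z <- stats::qnorm(1 - alpha / 2)
  list(ci_low = pooled - z * se, ci_high = pooled + z * se, se = se,
       p_value = 2 * stats::pnorm(-abs(pooled) / se))
}

#' Hartung-Knapp/Sidik-Jonkman confidence interval
#'
#' Small-sample interval for the random-effects pooled estimate: the
#' variance is rescaled by
#' \eqn{q = \sum W_k (y_k - \hat\mu)^2 / (K - 1)} (random-effects weights),
#' giving \eqn{\mathrm{Var}(\hat\mu) = q / \sum W_k}, and the reference
#' distribution is t with `K - 1` degrees of freedom. `q` is used
#' untruncated, so when all estimates coincide the interval degenerates to
#' zero width.
#'
#' @param input A [meta_input()].
#' @param tau2 Between-study variance used in the weights.
#' @param alpha Two-sided significance level.
#' @return List with `ci_low`, `ci_high`, `se`, `p_value`, `df`, `pooled`.
#' @export
hksj_ci <- function(input, tau2, alpha = 0.05) {
  stopifnot(inherits(input, "meta_input"), tau2 >= 0)
  if (input$k < 2L) stop("HKSJ requires at least 2 studies", call. = FALSE)
  re <- random_effects_pool(input, tau2)
  w <- re$weights
  q <- sum(w * (input$yi - re$pooled)^2) / (input$k - 1)
  v <- q / sum(w)
  se <- sqrt(v)
  df <- input$k - 1
  tq <- stats::qt(1 - alpha / 2, df)
  p <- if (se > 0) 2 * stats::pt(-abs(re$pooled) / se, df) else 0
  list(ci_low = re$pooled - tq * se, ci_high = re$pooled + tq * se,
       se = se, p_value = p, df = df, pooled = re$pooled)
}

new_meta_result <- function(model, tau2_method, ci_method, pooled, se_pooled,
                            ci_low, ci_high, p_value, alpha, tau2, Q, df,
                            converged, k, label) {
  structure(
    list(model = model, tau2_method = tau2_method, ci_method = ci_method,
         pooled = pooled, se_pooled = se_pooled, ci_low = ci_low,
         ci_high = ci_high, p_value = p_value, alpha = alpha, tau2 = tau2,
         Q = Q, df = df, converged = converged, k = k, label = label),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  lab <- if (x$model == "fixed") "Fixed-effect"
         else sprintf("Random-effects (%s + %s)", x$tau2_method, x$ci_method)
  cat(sprintf("%s meta-analysis of %d studies\n", lab, x$k))
  cat(sprintf("  pooled = %.4f (SE %.4f), %d%% CI (%.4f, %.4f), p = %.4g\n",
              x$pooled, x$se_pooled, round(100 * (1 - x$alpha)),
              x$ci_low, x$ci_high, x$p_value))
  if (x$model == "random")
    cat(sprintf("  tau2 = %.5f (%s%s), Q = %.3f\n", x$tau2, x$tau2_method,
                if (x$converged) "" else ", NOT converged", x$Q))
  invisible(x)
}

#' Two-stage univariate meta-analysis
#'
#' Dispatches to the pooling, between-study variance and interval methods.
#' The five combinations examined by the simulation framework are
#' fixed-effect (Wald-type interval) and the four random-effects pairings of
#' tau-squared estimator (DL, REML) with interval method (WT, HKSJ).
#'
#' @param input A [meta_input()].
#' @param model `"fixed"` or `"random"`.
#' @param tau2_method `"DL"` or `"REML"` (random-effects only).
#' @param ci_method `"WT"` or `"HKSJ"` (fixed-effect forces `"WT"`).
#' @param alpha Two-sided significance level.
#' @return An object of class `meta_result` with the pooled estimate, its
#'   standard error, confidence interval, p-value, `tau2`, Cochran `Q`, and
#'   a convergence flag (REML tau-squared only).
#' @export
#' @examples
#' inp <- meta_input(c(0.2, 0.5, 0.9), se = c(0.2, 0.25, 0.3))
#' meta_analyse(inp, model = "random", tau2_method = "DL", ci_method = "WT")
meta_analyse <- function(input, model = c("random", "fixed"),
                         tau2_method = c("DL", "REML"),
                         ci_method = c("WT", "HKSJ"), alpha = 0.05) {
  stopifnot(inherits(input, "meta_input"))
  model <- match.arg(model)
  if (model == "fixed") {
    if (!missing(ci_method) && match.arg(ci_method) != "WT")
      stop("fixed-effect model uses the Wald-type interval", call. = FALSE)
    return(fixed_effect_pool(input, alpha))
  }
  tau2_method <- match.arg(tau2_method)
  ci_method <- match.arg(ci_method)

  converged <- TRUE
  if (tau2_method == "DL") {
    est <- dl_tau2(input)
    tau2 <- est$tau2
    Q <- est$Q
  } else {
    est <- reml_tau2(input)
    tau2 <- est$tau2
    converged <- est$converged
    Q <- cochran_q(input)
  }
  re <- random_effects_pool(input, tau2)
  if (ci_method == "WT") {
    ci <- wt_ci(re$pooled, re$variance, alpha)
    df <- NA_real_
  } else {
    ci <- hksj_ci(input, tau2, alpha)
    df <- ci$df
  }
  new_meta_result(model = "random", tau2_method = tau2_method,
                  ci_method = ci_method, pooled = re$pooled, se_pooled = ci$se,
                  ci_low = ci$ci_low, ci_high = ci$ci_high,
                  p_value = ci$p_value, alpha = alpha, tau2 = tau2, Q = Q,
                  df = df, converged = converged, k = input$k,
                  label = input$label)
}

#' The five meta-analysis method combinations under evaluation
#'
#' @return Data frame with columns `model`, `tau2_method`, `ci_method` and a
#'   display `label`, one row per combination: fixed-effect, DL+WT, DL+HKSJ,
#'   REML+WT, REML+HKSJ.
#' @export
meta_method_grid <- function() {
  data.frame(
    model = c("fixed", "random", "random", "random", "random"),
    tau2_method = c("none", "DL", "DL", "REML", "REML"),
    ci_method = c("WT", "WT", "HKSJ", "WT", "HKSJ"),
    label = c("Fixed", "DL+WT", "DL+HKSJ", "REML+WT", "REML+HKSJ"),
    stringsAsFactors = FALSE
  )
}
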