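#' Monte Carlo standard error of a coverage (or rejection) percentage
#'
#' For a proportion reported in percent over `n_reps` replicates:
#' `sqrt(p * (100 - p) / n_reps)` percentage points. With 1000 replicates a
#' nominal 95% coverage has MCSE about 0.69 points, which is the usual
#' justification for that replicate count.
#'
#' @param pct Percentage in [0, 100].
#' @param n_reps Number of replicates.
#' @return MCSE in percentage points.
#' @export
#' @examples
#' mcse_percent(95, 1000)
mcse_percent <- function(pct, n_reps) {
  stopifnot(all(pct >= 0 & pct <= 100), n_reps > 0)
  sqrt(pct * (100 - pct) / n_reps)
}

record_group_cols <- c("scenario_id", "its_method", "meta_method", "effect")

#' Summarise replicate meta-analysis results into performance measures
#'
#' Computes, per (scenario, ITS analysis arm, meta-analysis method, effect
#' measure): bias, empirical SE (SD of the pooled estimates), model-based SE
#' (root mean square of the model SEs), their ratio, 95% CI coverage of the
#' true effect, the percentage of intervals excluding zero (power when the
#' true effect is non-zero, type I error when it is zero), tau-squared
#' summaries, and Monte Carlo standard errors for bias, coverage and power.
#'
#' Replicates whose REML tau-squared estimation failed to converge are
#' excluded from that method's summaries and counted in `n_nonconverged`.
#'
#' @param records Data frame of replicate records as produced by
#'   [run_replicate()]: one row per replicate x ITS arm x meta-method x
#'   effect, with columns `scenario_id`, `replicate`, `its_method`,
#'   `meta_method`, `effect`, `pooled`, `se_pooled`, `ci_low`, `ci_high`,
#'   `p_value`, `tau2`, `meta_converged`.
#' @param truth Named numeric vector giving the true (mean) effect for each
#'   effect measure, e.g. `c(level = 1, slope = 0.1)`. Under random-effects
#'   generation this is the mean of the effect distribution.
#' @return Data frame, one row per group, with the performance measures and
#'   their MCSEs.
#' @export
summarize_performance <- function(records, truth) {
  stopifnot(is.data.frame(records), !is.null(names(truth)))
  if (length(unique(records$scenario_id)) > 1L)
    stop("records mix scenario_ids; summarise one scenario at a time",
         call. = FALSE)
  missing_eff <- setdiff(unique(records$effect), names(truth))
  if (length(missing_eff))
    stop("no truth supplied for effect(s): ",
         paste(missing_eff, collapse = ", "), call. = FALSE)

  groups <- split(records, records[record_group_cols], drop = TRUE)
  out <- lapply(groups, function(g) {
    tv <- truth[[g$effect[1L]]]
    n_total <- nrow(g)
    conv <- g[g$meta_converged, , drop = FALSE]
    n <- nrow(conv)
    if (n < 2L)
      stop("fewer than 2 converged replicates in a group", call. = FALSE)
    bias <- mean(conv$pooled) - tv
    emp_se <- stats::sd(conv$pooled)
    mod_se <- sqrt(mean(conv$se_pooled^2))
    coverage <- 100 * mean(conv$ci_low <= tv & tv <= conv$ci_high)
    reject0 <- 100 * mean(conv$ci_low > 0 | conv$ci_high < 0)
    data.frame(
      scenario_id = g$scenario_id[1L], its_method = g$its_method[1L],
      meta_method = g$meta_method[1L], effect = g$effect[1L],
      truth = tv, n_reps = n, n_nonconverged = n_total - n,
      bias = bias, mcse_bias = emp_se / sqrt(n),
      emp_se = emp_se, mod_se = mod_se, mod_to_emp = mod_se / emp_se,
      coverage = coverage, mcse_coverage = mcse_percent(coverage, n),
      power_or_type1 = reject0, mcse_power = mcse_percent(reject0, n),
      tau2_mean = mean(conv$tau2), tau2_median = stats::median(conv$tau2),
      prop_tau2_positive = 100 * mean(conv$tau2 > 0),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$its_method, res$meta_method, res$effect), , drop = FALSE]
}

#' Tabulate non-convergence of the study-level and meta-level estimators
#'
#' Counts, per scenario and ITS analysis arm, how often the study-level fits
#' fell back from REML to Prais-Winsten or OLS, and how often the REML
#' tau-squared iteration at the meta-analysis level failed to converge.
#'
#' @param records Replicate records (see [summarize_performance()]), which
#'   must carry `n_studies`, `n_used_pw`, `n_used_ols` and `meta_converged`.
#' @return Data frame with per-(scenario, its_method) study-fit fallback
#'   counts and rates, and per-(scenario, its_method, meta_method)
#'   meta-level non-convergence pooled over meta-methods.
#' @export
tally_convergence <- function(records) {
  stopifnot(all(c("n_studies", "n_used_pw", "n_used_ols") %in%
                  names(records)))
  groups <- split(records, records[c("scenario_id", "its_method")],
                  drop = TRUE)
  out <- lapply(groups, function(g) {
    # study-level tallies are identical across the meta-method/effect rows
    # of one replicate; keep one row per replicate
    u <- g[!duplicated(g$replicate), , drop = FALSE]
    n_series <- sum(u$n_studies)
    data.frame(
      scenario_id = g$scenario_id[1L], its_method = g$its_method[1L],
      n_series = n_series,
      n_used_pw = sum(u$n_used_pw), n_used_ols = sum(u$n_used_ols),
      fallback_rate = 100 * sum(u$n_used_pw + u$n_used_ols) / n_series,
      n_meta = nrow(g), n_meta_nonconverged = sum(!g$meta_converged),
      meta_nonconvergence_rate = 100 * mean(!g$meta_converged),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
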