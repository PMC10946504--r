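#' Published state-level traffic-fatality interruption effect estimates
#'
#' Study-level segmented-regression results from a published analysis of the
#' effect of legalising recreational cannabis sales on monthly traffic
#' fatality rates (per million residents) in 11 US states (96 monthly data
#' points per series). For each state the immediate level-change and the
#' slope-change are given with standard errors, estimated both by OLS and
#' by REML with AR(1) errors, together with the REML autocorrelation
#' estimate. Values are as printed in the source (two decimals; one SE
#' printed to one decimal is carried as its two-decimal equivalent).
#'
#' @return Data frame with one row per state and columns `state`,
#'   `level_ols`, `level_ols_se`, `level_reml`, `level_reml_se`,
#'   `slope_ols`, `slope_ols_se`, `slope_reml`, `slope_reml_se`,
#'   `autocorrelation`.
#' @export
#' @examples
#' head(traffic_fatality_estimates())
traffic_fatality_estimates <- function() {
  path <- system.file("extdata", "traffic_fatality_estimates.csv",
                      package = "metaits", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Worked meta-analysis of the traffic-fatality example
#'
#' Pools the 11 state-level estimates with all five meta-analysis method
#' combinations, separately for each ITS analysis arm (OLS, REML) and each
#' effect measure (level-change, slope-change): 20 meta-analyses in all.
#' Because the inputs are the printed two-decimal estimates, results can
#' differ from those computed from unrounded study-level fits by about
#' 0.01 (0.003 for the between-study variance).
#'
#' @param alpha Two-sided significance level (default 0.05).
#' @return Data frame with one row per (ITS arm, effect, meta-method):
#'   pooled estimate, CI bounds, p-value and tau-squared.
#' @export
#' @examples
#' ex <- fatality_meta_example()
#' subset(ex, its_method == "OLS" & effect == "level")
fatality_meta_example <- function(alpha = 0.05) {
  est <- traffic_fatality_estimates()
  methods <- meta_method_grid()
  cols <- list(
    list(its_method = "OLS", effect = "level",
         yi = est$level_ols, sei = est$level_ols_se),
    list(its_method = "REML", effect = "level",
         yi = est$level_reml, sei = est$level_reml_se),
    list(its_method = "OLS", effect = "slope",
         yi = est$slope_ols, sei = est$slope_ols_se),
    list(its_method = "REML", effect = "slope",
         yi = est$slope_reml, sei = est$slope_reml_se)
  )
  rows <- list()
  for (cc in cols) {
    inp <- meta_input(cc$yi, se = cc$sei, label = cc$effect)
    for (m in seq_len(nrow(methods))) {
      mm <- methods[m, ]
      res <- meta_analyse(inp, model = mm$model,
                          tau2_method = if (mm$model == "fixed") "DL"
                                        else mm$tau2_method,
                          ci_method = mm$ci_method, alpha = alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        its_method = cc$its_method, effect = cc$effect,
        meta_method = mm$label, pooled = res$pooled,
        se_pooled = res$se_pooled, ci_low = res$ci_low,
        ci_high = res$ci_high, p_value = res$p_value, tau2 = res$tau2,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
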