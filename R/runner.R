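#' Configure a factorial simulation grid
#'
#' Factor levels for the fully crossed simulation design. The defaults are
#' the study grid: series lengths 12/48/100, autocorrelation 0/0.2/0.4/0.6
#' or variable (Normal(0.4, 0.15^2) per study), level-change 0/1,
#' slope-change 0/0.1, 3/5/20 studies per meta-analysis, level-change
#' between-study variance 0/0.1^2/0.3^2 and slope-change between-study
#' variance 0/0.01^2/0.05^2 — 1620 scenarios in all.
#'
#' @param n_obs Series lengths.
#' @param rho Autocorrelation levels; numeric values and/or `"variable"`.
#' @param beta2,beta3 True mean level- and slope-changes.
#' @param K Numbers of studies per meta-analysis.
#' @param tau2_level,tau2_slope Between-study variances.
#' @param n_reps Replicates per scenario.
#' @param seed Base seed; every (scenario, replicate) derives its own
#'   reproducible stream from it.
#' @param its_methods ITS analysis arms: `"OLS"` (plain OLS) and/or
#'   `"REML"` (the REML -> PW -> OLS cascade).
#' @param meta_methods Data frame of meta-method combinations (default: the
#'   five from [meta_method_grid()]).
#' @return An object of class `grid_config`.
#' @export
#' @examples
#' nrow(enumerate_scenarios(grid_config()))  # 1620
grid_config <- function(n_obs = c(12, 48, 100),
                        rho = list(0, 0.2, 0.4, 0.6, "variable"),
                        beta2 = c(0, 1), beta3 = c(0, 0.1),
                        K = c(3, 5, 20),
                        tau2_level = c(0, 0.1^2, 0.3^2),
                        tau2_slope = c(0, 0.01^2, 0.05^2),
                        n_reps = 1000, seed = 1L,
                        its_methods = c("OLS", "REML"),
                        meta_methods = meta_method_grid()) {
  if (!is.list(rho)) rho <- as.list(rho)
  lens <- list(n_obs = n_obs, rho = rho, beta2 = beta2, beta3 = beta3,
               K = K, tau2_level = tau2_level, tau2_slope = tau2_slope)
  bad <- names(lens)[vapply(lens, length, 1L) == 0L]
  if (length(bad))
    stop("empty factor level(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  its_methods <- match.arg(its_methods, c("OLS", "REML"), several.ok = TRUE)
  structure(
    list(n_obs = n_obs, rho = rho, beta2 = beta2, beta3 = beta3, K = K,
         tau2_level = tau2_level, tau2_slope = tau2_slope,
         n_reps = as.integer(n_reps), seed = as.integer(seed),
         its_methods = its_methods, meta_methods = meta_methods),
    class = "grid_config"
  )
}

#' Enumerate the scenarios of a grid configuration
#'
#' Cartesian product of the factor levels in a deterministic order, with
#' stable zero-padded scenario identifiers.
#'
#' @param config A [grid_config()].
#' @return Data frame, one row per scenario, with columns `scenario_id`,
#'   `scenario_index`, the factor levels (`rho` is the string `"variable"`
#'   for the variable-autocorrelation level) and `n_reps`.
#' @export
enumerate_scenarios <- function(config) {
  stopifnot(inherits(config, "grid_config"))
  rho_labels <- vapply(config$rho, function(r)
    if (identical(r, "variable")) "variable" else format(r), character(1))
  g <- expand.grid(
    tau2_slope = config$tau2_slope, tau2_level = config$tau2_level,
    K = config$K, beta3 = config$beta3, beta2 = config$beta2,
    rho = rho_labels, n_obs = config$n_obs,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  # reorder columns: slowest-varying factor first
  g <- g[, c("n_obs", "rho", "beta2", "beta3", "K", "tau2_level",
             "tau2_slope")]
  g$scenario_index <- seq_len(nrow(g))
  g$scenario_id <- sprintf("S%04d", g$scenario_index)
  g$n_reps <- config$n_reps
  rownames(g) <- NULL
  g[, c("scenario_id", "scenario_index", "n_obs", "rho", "beta2", "beta3",
        "K", "tau2_level", "tau2_slope", "n_reps")]
}

scenario_from_row <- function(row, config) {
  rho <- if (identical(row$rho, "variable")) "variable" else
    as.numeric(row$rho)
  scenario_spec(n_obs = row$n_obs, beta2 = row$beta2, beta3 = row$beta3,
                rho = rho, K = row$K, tau2_level = row$tau2_level,
                tau2_slope = row$tau2_slope, n_reps = row$n_reps,
                seed = config$seed)
}

# Deterministic per-(scenario, replicate) seed derived from the base seed by
# Lehmer-style mixing; keeps every derived seed inside the 32-bit integer
# range and makes replicates independent of execution order and of worker
# assignment.
derive_seed <- function(base, scenario_index, replicate) {
  m <- 2147483647
  s <- (((abs(base) %% (m - 1)) + 1) * 48271) %% m
  s <- (((s + scenario_index) %% (m - 1) + 1) * 48271) %% m
  s <- (((s + replicate) %% (m - 1) + 1) * 48271) %% m
  as.integer(s)
}

fit_arm <- function(series, its_method) {
  if (its_method == "OLS") fit_ols(series) else fit_cascade(series)
}

#' Run one replicate of a scenario
#'
#' Generates one meta-analysis sample, fits every study with each ITS
#' analysis arm (both arms see the identical data — a paired design), pools
#' the level-change and slope-change estimates with each meta-analysis
#' method, and returns one record per (arm x meta-method x effect).
#'
#' @param spec A [scenario_spec()].
#' @param replicate Replicate index (also keys the random stream).
#' @param its_methods Character vector of arms (`"OLS"`, `"REML"`).
#' @param meta_methods Data frame of method combinations
#'   ([meta_method_grid()] format).
#' @param scenario_index,scenario_id Identifiers used for seeding and
#'   labelling.
#' @return Data frame of replicate records (see
#'   [summarize_performance()] for the column contract).
#' @export
run_replicate <- function(spec, replicate, its_methods = c("OLS", "REML"),
                          meta_methods = meta_method_grid(),
                          scenario_index = 1L, scenario_id = "S0001") {
  set.seed(derive_seed(spec$seed, scenario_index, replicate))
  sample <- generate_meta_sample(spec)

  out <- vector("list", length(its_methods))
  for (a in seq_along(its_methods)) {
    arm <- its_methods[a]
    fits <- lapply(sample$series, fit_arm, its_method = arm)
    used <- vapply(fits, function(f) f$method_used, character(1))
    n_used_pw <- sum(used == "PW")
    n_used_ols <- if (arm == "OLS") 0L else sum(used == "OLS")

    rows <- vector("list", 2L * nrow(meta_methods))
    r <- 0L
    for (effect in c("level", "slope")) {
      idx <- if (effect == "level") 3L else 4L
      inp <- meta_input(
        vapply(fits, function(f) f$beta_hat[idx], numeric(1)),
        se = vapply(fits, function(f) f$se[idx], numeric(1)),
        label = effect
      )
      for (m in seq_len(nrow(meta_methods))) {
        mm <- meta_methods[m, ]
        res <- meta_analyse(inp, model = mm$model,
                            tau2_method = if (mm$model == "fixed") "DL"
                                          else mm$tau2_method,
                            ci_method = mm$ci_method)
        r <- r + 1L
        rows[[r]] <- data.frame(
          scenario_id = scenario_id, replicate = replicate,
          its_method = arm, meta_method = mm$label, effect = effect,
          pooled = res$pooled, se_pooled = res$se_pooled,
          ci_low = res$ci_low, ci_high = res$ci_high,
          p_value = res$p_value, tau2 = res$tau2,
          meta_converged = res$converged,
          n_studies = spec$K, n_used_pw = n_used_pw,
          n_used_ols = n_used_ols, stringsAsFactors = FALSE
        )
      }
    }
    out[[a]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

run_scenario <- function(row, config) {
  spec <- scenario_from_row(row, config)
  recs <- lapply(seq_len(spec$n_reps), function(rep)
    run_replicate(spec, rep, its_methods = config$its_methods,
                  meta_methods = config$meta_methods,
                  scenario_index = row$scenario_index,
                  scenario_id = row$scenario_id))
  do.call(rbind, recs)
}

#' Execute a simulation grid
#'
#' Runs every scenario of the configuration, writes replicate-level records,
#' per-scenario performance summaries, and convergence tallies as CSV files.
#' Completed scenarios are check-pointed: rerunning with the same `out_dir`
#' skips scenarios already present in `replicates.csv`, so an interrupted
#' run can resume without duplicating work.
#'
#' @param config A [grid_config()].
#' @param out_dir Output directory (created if needed); set `NULL` to skip
#'   writing and just return the results.
#' @param verbose Print per-scenario progress.
#' @return Invisibly, a list with `replicates`, `summary` and `convergence`
#'   data frames.
#' @export
#' @examples
#' cfg <- grid_config(n_obs = 12, rho = list(0), beta2 = 1, beta3 = 0,
#'                    K = 3, tau2_level = 0, tau2_slope = 0, n_reps = 5)
#' res <- run_grid(cfg, out_dir = NULL, verbose = FALSE)
#' nrow(res$replicates)  # 5 reps x 2 arms x 5 methods x 2 effects
run_grid <- function(config, out_dir = "results", verbose = TRUE) {
  stopifnot(inherits(config, "grid_config"))
  scenarios <- enumerate_scenarios(config)

  rep_path <- sum_path <- conv_path <- NULL
  done <- character(0)
  prior <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    rep_path <- file.path(out_dir, "replicates.csv")
    sum_path <- file.path(out_dir, "summary.csv")
    conv_path <- file.path(out_dir, "convergence.csv")
    if (file.exists(rep_path)) {
      prior <- utils::read.csv(rep_path, stringsAsFactors = FALSE)
      done <- unique(prior$scenario_id)
    }
  }

  rep_list <- if (is.null(prior)) list() else list(prior)
  for (i in seq_len(nrow(scenarios))) {
    row <- scenarios[i, ]
    if (row$scenario_id %in% done) next
    t0 <- proc.time()[["elapsed"]]
    recs <- run_scenario(row, config)
    rep_list[[length(rep_list) + 1L]] <- recs
    if (!is.null(rep_path)) {
      utils::write.table(recs, rep_path, sep = ",", row.names = FALSE,
                         col.names = !file.exists(rep_path), append =
                           file.exists(rep_path))
    }
    if (verbose)
      message(sprintf("%s (%d/%d) done in %.1fs", row$scenario_id, i,
                      nrow(scenarios), proc.time()[["elapsed"]] - t0))
  }
  replicates <- do.call(rbind, rep_list)

  truth_for <- function(sid) {
    row <- scenarios[scenarios$scenario_id == sid, ]
    c(level = row$beta2, slope = row$beta3)
  }
  summaries <- do.call(rbind, lapply(unique(replicates$scenario_id),
    function(sid) summarize_performance(
      replicates[replicates$scenario_id == sid, , drop = FALSE],
      truth_for(sid))))
  convergence <- do.call(rbind, lapply(unique(replicates$scenario_id),
    function(sid) tally_convergence(
      replicates[replicates$scenario_id == sid, , drop = FALSE])))
  rownames(summaries) <- rownames(convergence) <- NULL

  if (!is.null(out_dir)) {
    utils::write.csv(summaries, sum_path, row.names = FALSE)
    utils::write.csv(convergence, conv_path, row.names = FALSE)
  }
  invisible(list(replicates = replicates, summary = summaries,
                 convergence = convergence))
}

#' Large-sample consistency check of the generation and estimation chain
#'
#' Generates meta-analysis samples with very long series and many studies,
#' fits each study, and checks that the recovered level-change,
#' slope-change, autocorrelation and between-study variances agree with the
#' generating values — the standard pre-flight consistency check for a
#' simulation study. Averages over `n_reps` replicate meta-samples to pin
#' down the between-study variance recovery (a single sample of `K` studies
#' estimates tau-squared with relative error about `sqrt(2/(K-1))`).
#'
#' Autocorrelation recovery uses REML fits on a subset of
#' `n_reml_series` series (REML on a 100,000-point series is fast but not
#' free; the autocorrelation estimate is already precise from a handful of
#' series at this length).
#'
#' @param n_obs Series length (default 1e5).
#' @param K Studies per meta-analysis (default 50).
#' @param n_reps Replicate meta-samples to average over (default 20).
#' @param beta2,beta3,rho,tau2_level,tau2_slope Generating values.
#' @param n_reml_series Number of series fitted by REML for the
#'   autocorrelation check.
#' @param seed Base seed.
#' @return Data frame with one row per checked quantity: generating value,
#'   recovered value, absolute and relative error.
#' @export
run_sanity <- function(n_obs = 1e5, K = 50, n_reps = 20,
                       beta2 = 1, beta3 = 0.1, rho = 0.4,
                       tau2_level = 0.3^2, tau2_slope = 0.05^2,
                       n_reml_series = 5, seed = 1L) {
  spec <- scenario_spec(n_obs = n_obs, beta2 = beta2, beta3 = beta3,
                        rho = rho, K = K, tau2_level = tau2_level,
                        tau2_slope = tau2_slope, n_reps = n_reps,
                        seed = seed)
  lev_pooled <- slp_pooled <- tau2_lev <- tau2_slp <- numeric(n_reps)
  rho_hats <- numeric(0)
  for (rep in seq_len(n_reps)) {
    set.seed(derive_seed(seed, 0L, rep))
    sample <- generate_meta_sample(spec)
    fits <- lapply(sample$series, fit_ols)
    lev <- meta_input(vapply(fits, function(f) f$beta_hat[3L], numeric(1)),
                      se = vapply(fits, function(f) f$se[3L], numeric(1)))
    slp <- meta_input(vapply(fits, function(f) f$beta_hat[4L], numeric(1)),
                      se = vapply(fits, function(f) f$se[4L], numeric(1)))
    lev_pooled[rep] <- random_effects_pool(lev, reml_tau2(lev)$tau2)$pooled
    slp_pooled[rep] <- random_effects_pool(slp, reml_tau2(slp)$tau2)$pooled
    tau2_lev[rep] <- reml_tau2(lev)$tau2
    tau2_slp[rep] <- reml_tau2(slp)$tau2
    if (rep == 1L) {
      rho_hats <- vapply(sample$series[seq_len(min(n_reml_series, K))],
                         function(s) fit_reml(s)$rho_hat, numeric(1))
    }
  }
  recovered <- c(mean(lev_pooled), mean(slp_pooled), mean(rho_hats),
                 mean(tau2_lev), mean(tau2_slp))
  true_vals <- c(beta2, beta3, rho, tau2_level, tau2_slope)
  data.frame(
    quantity = c("level_change", "slope_change", "autocorrelation",
                 "tau2_level", "tau2_slope"),
    true_value = true_vals, recovered = recovered,
    abs_error = abs(recovered - true_vals),
    rel_error = ifelse(true_vals != 0,
                       abs(recovered - true_vals) / abs(true_vals), NA),
    stringsAsFactors = FALSE
  )
}

#' Heterogeneity-detection sweep under no true level-change heterogeneity
#'
#' Reproduces the no-heterogeneity sweep: the 45 scenarios with a
#' level-change of 1, slope-change of 0.1, zero level-change between-study
#' variance and `K` studies per meta-analysis (series length 12/48/100 x
#' autocorrelation 0/0.2/0.4/0.6/variable x slope-change between-study
#' variance 0/0.01^2/0.05^2). Each replicate's studies are fitted with the
#' chosen ITS arm and the level-change estimates pooled with the REML
#' between-study variance estimator; the quantity of interest is how often
#' the estimated between-study variance exceeds zero even though the true
#' value is zero (spurious heterogeneity induced by underestimated
#' within-study standard errors).
#'
#' @param K Studies per meta-analysis.
#' @param n_reps Replicates per scenario.
#' @param seed Base seed.
#' @param its_method `"OLS"` or `"REML"` (cascade) study-level analysis.
#' @return List with `per_scenario` (data frame of per-scenario percentages
#'   of replicates with positive estimated between-study variance) and
#'   `pooled_pct` (the percentage pooled over all scenarios).
#' @export
run_tau2_sweep <- function(K = 3, n_reps = 200, seed = 1L,
                           its_method = "OLS") {
  mm <- meta_method_grid()
  cfg <- grid_config(
    n_obs = c(12, 48, 100), rho = list(0, 0.2, 0.4, 0.6, "variable"),
    beta2 = 1, beta3 = 0.1, K = K, tau2_level = 0,
    tau2_slope = c(0, 0.01^2, 0.05^2), n_reps = n_reps, seed = seed,
    its_methods = its_method,
    meta_methods = mm[mm$label == "REML+WT", , drop = FALSE]
  )
  res <- run_grid(cfg, out_dir = NULL, verbose = FALSE)
  lev <- res$replicates[res$replicates$effect == "level", , drop = FALSE]
  per <- aggregate(list(pct_tau2_positive = 100 * (lev$tau2 > 0)),
                   by = lev["scenario_id"], FUN = mean)
  list(per_scenario = per, pooled_pct = 100 * mean(lev$tau2 > 0))
}
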