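#' Project the fitted model over a forecast horizon
#'
#' Re-simulates the fitted model from the first fitted year through
#' `horizon_end`, extending the fitted rate surfaces by the carry-forward
#' rule ([extend_forecast()]) and taking the boundary inflow for forecast
#' years from the exogenous projected-population table (its youngest
#' modelled age). Historical years reproduce the fitted expectations
#' exactly. Results are summarized per calendar year and age group:
#' expected incident cases and cancer deaths, incidence and mortality per
#' 100,000 (using the model population of the same stratum), current- and
#' ex-smoker prevalence, and population size. An `"all"` group spanning
#' the whole grid is always included.
#'
#' When `n_boot > 0`, parameter vectors are resampled by
#' [parametric_bootstrap()] and the projection repeated per draw; per-row
#' percentile bands for cases and deaths are appended and the replicate
#' trajectories retained (for [find_peak()] interval estimates).
#'
#' @param fit an `lc_fit`.
#' @param projected_population table with columns `sex`, `year`, `age_lo`,
#'   `age_hi`, `count` covering the forecast years; defaults to the one in
#'   the fit's observation set.
#' @param horizon_end last forecast calendar year (must be covered by the
#'   projection table).
#' @param age_groups named list of `c(lo, hi)` closed-open age intervals;
#'   default the reporting groups 15-64, 65-74, 75+.
#' @param n_boot number of bootstrap replicates (0 = point forecast only).
#' @param seed seed for the bootstrap (required when `n_boot > 0`).
#' @param level band coverage (default 0.95).
#' @return An object of class `lc_forecast`: a data frame with columns
#'   `sex`, `year`, `age_group`, `cases`, `deaths`, `incidence_per_1e5`,
#'   `mortality_per_1e5`, `smoker_prev`, `exsmoker_prev`, `population`
#'   (plus `*_lower` / `*_upper` band columns when bootstrapped), carrying
#'   the replicate ensemble as an attribute.
#' @export
project_burden <- function(fit, projected_population = NULL, horizon_end,
                           age_groups = NULL, n_boot = 0, seed = NULL,
                           level = 0.95) {
  if (!inherits(fit, "lc_fit")) stop("`fit` must be an `lc_fit`", call. = FALSE)
  proj <- projected_population %||% fit$obs$projected_population
  if (is.null(proj))
    stop("no projected population available for the forecast", call. = FALSE)
  age_groups <- age_groups %||% .default_age_groups()
  tab <- .project_theta(fit$theta_hat, fit, fit$fixed, proj, horizon_end,
                        age_groups)
  ensemble <- NULL
  if (n_boot > 0) {
    if (is.null(seed))
      stop("`seed` is required when bootstrapping the forecast", call. = FALSE)
    boot <- parametric_bootstrap(
      fit, n_reps = n_boot, seed = seed, level = level,
      output_fn = function(theta) {
        rep_tab <- .project_theta(theta, fit, fit$fixed, proj, horizon_end,
                                  age_groups)
        c(rep_tab$cases, rep_tab$deaths)
      })
    m <- nrow(tab)
    ensemble <- list(cases = boot$outputs[, seq_len(m), drop = FALSE],
                     deaths = boot$outputs[, m + seq_len(m), drop = FALSE],
                     seed = seed, level = level)
    alpha <- (1 - level) / 2
    qs <- function(x) apply(x, 2, quantile, probs = c(alpha, 1 - alpha),
                            names = FALSE)
    bc <- qs(ensemble$cases); bd <- qs(ensemble$deaths)
    tab$cases_lower <- bc[1, ]; tab$cases_upper <- bc[2, ]
    tab$deaths_lower <- bd[1, ]; tab$deaths_upper <- bd[2, ]
  }
  structure(tab, ensemble = ensemble, age_groups = age_groups,
            class = c("lc_forecast", "data.frame"))
}

.default_age_groups <- function() {
  list("15-64" = c(15, 65), "65-74" = c(65, 75), "75+" = c(75, Inf))
}

# one projection run for a given parameter vector and hazard ratios
.project_theta <- function(theta, fit, fixed, proj, horizon_end, age_groups) {
  g <- fit$blocks$grid
  horizon_end <- as.integer(horizon_end)
  if (horizon_end < g$t_max)
    stop("`horizon_end` must not precede the last fitted year", call. = FALSE)
  sim_end <- horizon_end + 1L
  rates <- extend_forecast(expand_rates(theta, fit$blocks), g$t_max, sim_end)
  sim_grid <- attr(rates, "grid")

  proj <- proj[proj$sex == g$sex, , drop = FALSE]
  inflow <- .forecast_inflow(fit, proj, g, sim_end)
  init <- population_state(g$t0, fit$inputs$initial_state$counts, sim_grid)
  traj <- simulate_population(rates, fixed, init, inflow)
  .summarize_trajectory(traj, g$t0, horizon_end, age_groups)
}

.forecast_inflow <- function(fit, proj, g, sim_end) {
  hist_years <- (g$t0 + 1L):g$t_max
  hist <- setNames(.resolve_inflow(fit$inputs$inflow, hist_years),
                   hist_years)
  fut_years <- (g$t_max + 1L):sim_end
  at_a0 <- proj[proj$age_lo == g$a0, , drop = FALSE]
  fut <- setNames(at_a0$count[match(fut_years, at_a0$year)], fut_years)
  # the state one year past the horizon is discarded; tolerate a missing
  # final projection year by carrying the last available inflow
  if (is.na(fut[[length(fut)]]) && length(fut) > 1L)
    fut[[length(fut)]] <- fut[[length(fut) - 1L]]
  if (anyNA(fut))
    stop(sprintf("projected population does not cover forecast years: %s",
                 paste(fut_years[is.na(fut)], collapse = ", ")), call. = FALSE)
  c(hist, fut)
}

.summarize_trajectory <- function(traj, first_year, last_year, age_groups) {
  g <- traj$grid
  groups <- c(age_groups, list(all = c(g$a0, Inf)))
  years <- first_year:last_year
  ages <- grid_ages(g)
  rows <- list()
  for (gi in seq_along(groups)) {
    lo <- max(groups[[gi]][1], g$a0)
    hi <- min(groups[[gi]][2] - 1, g$a_max)
    sel <- which(ages >= lo & ages <= hi)
    y_idx <- years - g$t0 + 1L
    cases <- apply(traj$flows["new_cases", sel, y_idx, drop = FALSE], 3, sum)
    deaths <- apply(traj$flows["cancer_deaths", sel, y_idx, drop = FALSE], 3, sum)
    pop <- apply(traj$states[, sel, y_idx, drop = FALSE], 3, sum)
    smk <- apply(traj$states["S", sel, y_idx, drop = FALSE], 3, sum)
    exs <- apply(traj$states["E", sel, y_idx, drop = FALSE], 3, sum)
    rows[[gi]] <- data.frame(
      sex = g$sex, year = years, age_group = names(groups)[gi],
      cases = as.numeric(cases), deaths = as.numeric(deaths),
      incidence_per_1e5 = 1e5 * as.numeric(cases) / pop,
      mortality_per_1e5 = 1e5 * as.numeric(deaths) / pop,
      smoker_prev = smk / pop, exsmoker_prev = exs / pop,
      population = pop, row.names = NULL
    )
  }
  do.call(rbind, rows)
}

#' Locate the peak of a yearly burden series
#'
#' Returns the maximum of a yearly series and its calendar year, breaking
#' ties toward the earliest year. An all-equal series is flagged `flat`
#' and a maximum attained in the final year is flagged `boundary`. When a
#' bootstrap ensemble of replicate series is supplied, the interval
#' estimate of the peak value is formed from the percentiles of the
#' per-replicate maxima (each replicate trajectory contributes its own
#' maximum), and likewise for the peak year.
#'
#' @param series numeric vector of yearly values.
#' @param years calendar years aligned with `series`.
#' @param ensemble optional `n_reps x length(series)` matrix of replicate
#'   series.
#' @param level interval coverage (default 0.95).
#' @return An object of class `lc_peak`: `peak_year`, `peak_value`,
#'   `value_ci`, `year_ci` (or `NULL` without an ensemble) and `flags`.
#' @export
find_peak <- function(series, years, ensemble = NULL, level = 0.95) {
  if (!length(series)) stop("`series` is empty", call. = FALSE)
  if (length(series) != length(years))
    stop("`series` and `years` lengths differ", call. = FALSE)
  i <- which.max(series)      # earliest index on ties
  flags <- character()
  if (all(series == series[1L])) flags <- c(flags, "flat")
  if (i == length(series)) flags <- c(flags, "boundary")
  value_ci <- year_ci <- NULL
  if (!is.null(ensemble)) {
    if (ncol(ensemble) != length(series))
      stop("`ensemble` columns must align with `series`", call. = FALSE)
    alpha <- (1 - level) / 2
    maxima <- apply(ensemble, 1, max)
    argmax <- years[apply(ensemble, 1, which.max)]
    value_ci <- unname(quantile(maxima, c(alpha, 1 - alpha)))
    year_ci <- unname(quantile(argmax, c(alpha, 1 - alpha), type = 1))
  }
  structure(list(peak_year = years[i], peak_value = series[i],
                 value_ci = value_ci, year_ci = year_ci, flags = flags),
            class = "lc_peak")
}

#' @export
print.lc_peak <- function(x, ...) {
  cat(sprintf("<lc_peak> year %d, value %.6g%s\n", x$peak_year, x$peak_value,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
              else ""))
  if (!is.null(x$value_ci))
    cat(sprintf("  value CI [%.6g, %.6g]; year CI [%d, %d]\n",
                x$value_ci[1], x$value_ci[2], x$year_ci[1], x$year_ci[2]))
  invisible(x)
}

#' Peak summary of a forecast output
#'
#' Convenience wrapper running [find_peak()] on one output series of an
#' [project_burden()] result, using its bootstrap ensemble when present.
#'
#' @param forecast an `lc_forecast`.
#' @param output `"cases"` or `"deaths"`.
#' @param group age-group label present in the forecast (default `"all"`).
#' @param level interval coverage.
#' @return An `lc_peak`.
#' @export
peak_summary <- function(forecast, output = c("cases", "deaths"),
                         group = "all", level = 0.95) {
  output <- match.arg(output)
  if (!inherits(forecast, "lc_forecast"))
    stop("`forecast` must come from `project_burden()`", call. = FALSE)
  sel <- forecast$age_group == group
  if (!any(sel)) stop(sprintf("no age group `%s` in the forecast", group),
                      call. = FALSE)
  ens <- attr(forecast, "ensemble")
  ens_mat <- if (!is.null(ens)) ens[[output]][, sel, drop = FALSE]
  find_peak(forecast[[output]][sel], forecast$year[sel], ens_mat, level)
}

#' Sensitivity of the forecast to the smoker hazard ratio
#'
#' Re-simulates the fitted model with the current-smoker lung cancer
#' hazard ratio `kS` multiplied by each value in `multipliers`, holding
#' every estimated parameter (and `kE`, `qS`, `qE`) at its fitted value —
#' the model is not refitted. A multiplier of 1 reproduces the baseline
#' projection exactly.
#'
#' @inheritParams project_burden
#' @param multipliers positive multipliers applied to `kS`
#'   (default `c(0.5, 1, 1.5)`).
#' @return A data frame of class `lc_sensitivity`: the
#'   [project_burden()] summary rows for every multiplier, with a
#'   `ks_multiplier` column.
#' @export
sensitivity_ks <- function(fit, multipliers = c(0.5, 1, 1.5),
                           projected_population = NULL, horizon_end,
                           age_groups = NULL) {
  if (!inherits(fit, "lc_fit")) stop("`fit` must be an `lc_fit`", call. = FALSE)
  if (any(!is.finite(multipliers)) || any(multipliers <= 0))
    stop("`multipliers` must be positive", call. = FALSE)
  proj <- projected_population %||% fit$obs$projected_population
  if (is.null(proj))
    stop("no projected population available for the forecast", call. = FALSE)
  age_groups <- age_groups %||% .default_age_groups()
  out <- lapply(multipliers, function(m) {
    hr <- hazard_ratios(fit$fixed$kS * m, fit$fixed$kE, fit$fixed$qS,
                        fit$fixed$qE)
    tab <- .project_theta(fit$theta_hat, fit, hr, proj, horizon_end,
                          age_groups)
    tab$ks_multiplier <- m
    tab
  })
  structure(do.call(rbind, out), class = c("lc_sensitivity", "data.frame"))
}
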