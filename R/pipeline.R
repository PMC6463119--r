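#' Read and write initial population states
#'
#' The initial state at the first fitted year is an exogenous input (the
#' smoking-status split of the population at `t0`). On disk it is a CSV
#' with columns `sex`, `age`, `M`, `S`, `E`, `L`.
#'
#' @param states named list of [population_state()] objects (one per sex).
#' @param path CSV file path.
#' @return `read_initial_states()` returns a named list of `4 x n_ages`
#'   count matrices by sex (ages as column names).
#' @export
write_initial_states <- function(states, path) {
  rows <- lapply(states, function(st) {
    data.frame(sex = st$grid$sex, age = grid_ages(st$grid),
               M = st$counts["M", ], S = st$counts["S", ],
               E = st$counts["E", ], L = st$counts["L", ])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_initial_states
#' @export
read_initial_states <- function(path) {
  tab <- read.csv(path)
  need <- c("sex", "age", "M", "S", "E", "L")
  if (!all(need %in% names(tab)))
    stop(sprintf("initial-state file must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  out <- lapply(split(tab, tab$sex), function(d) {
    d <- d[order(d$age), ]
    m <- t(as.matrix(d[, c("M", "S", "E", "L")]))
    dimnames(m) <- list(compartment = .compartments, age = d$age)
    m
  })
  out
}

#' Serialize a fit result to JSON
#'
#' Writes the estimate, log-likelihood, convergence diagnostics and
#' parameter covariance of an `lc_fit` to a documented JSON file.
#'
#' @param fit an `lc_fit`.
#' @param path output file.
#' @export
write_fit_json <- function(fit, path) {
  g <- fit$blocks$grid
  payload <- list(
    sex = g$sex,
    grid = list(t0 = g$t0, t_max = g$t_max, a0 = g$a0, a_max = g$a_max),
    loglik = fit$loglik,
    convergence = fit$convergence,
    psd_repaired = fit$psd_repaired,
    fixed = unclass(fit$fixed),
    theta_hat = as.list(fit$theta_hat),
    covariance = if (!is.null(fit$covariance)) unname(fit$covariance)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full estimation and forecasting pipeline
#'
#' Executes the stages in order — validate the observed tables, fit each
#' sex by maximum likelihood, bootstrap and project the burden over the
#' forecast horizon, locate the peak years of cases and deaths, and sweep
#' the `kS` sensitivity — writing per-stage artifacts and a JSON summary
#' when an output directory is given. The run is fully determined by the
#' configuration and seed.
#'
#' @param config a named list (or path to a YAML file) with elements:
#'   `obs` (an [observation_set()]) or `data_dir` (directory of CSVs);
#'   `inputs` (named per-sex list of [model_inputs()]) or
#'   `initial_states` (path to a CSV readable by [read_initial_states()],
#'   with inflow taken from the population table at the youngest age);
#'   `t0`, `t_max` (fitting window; defaults to the population table's
#'   span); `horizon_end`; `sexes` (default: those present in `inputs`);
#'   `fixed` (per-sex [hazard_ratios()]; literature defaults);
#'   `age_edges`, `time_edges`, `time_block_width` (block structure);
#'   `n_boot` (default 0: point forecasts only), `seed`,
#'   `multipliers` (default `c(0.5, 1, 1.5)`), `age_groups`,
#'   `control` (optimizer settings), `out_dir` (optional).
#' @return A report list with per-sex fit diagnostics, peak summaries,
#'   and the forecast and sensitivity tables; written artifacts when
#'   `out_dir` is set (`fit_<sex>.json`, `forecast.csv`,
#'   `sensitivity.csv`, `report.json`, `config.yaml`, `run.log`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("`config` must be a list or YAML path",
                             call. = FALSE)
  log_lines <- c(sprintf("lcforecast %s; R %s",
                         as.character(utils::packageVersion("lcforecast")),
                         paste(R.version$major, R.version$minor, sep = ".")))
  say <- function(fmt, ...) log_lines <<- c(log_lines, sprintf(fmt, ...))

  obs <- config$obs %||% read_observations(config$data_dir)
  validate_observations(obs)
  say("validated observation set")

  pop <- obs$population
  t0 <- config$t0 %||% min(pop$year)
  t_max <- config$t_max %||% max(pop$year)
  horizon_end <- config$horizon_end %||% t_max
  seed <- as.integer(config$seed %||% 1L)
  n_boot <- config$n_boot %||% 0L
  multipliers <- config$multipliers %||% c(0.5, 1, 1.5)
  age_groups <- config$age_groups %||% .default_age_groups()

  init_counts <- if (!is.null(config$initial_states))
    read_initial_states(config$initial_states)
  sexes <- config$sexes %||% names(config$inputs) %||% names(init_counts)
  if (is.null(sexes))
    stop("cannot determine sexes: supply `inputs`, `initial_states` or `sexes`",
         call. = FALSE)

  report <- list(seed = seed, n_boot = n_boot,
                 horizon_end = horizon_end, sexes = list())
  forecasts <- list(); sensitivities <- list(); fits <- list()
  for (i in seq_along(sexes)) {
    sx <- sexes[[i]]
    grid <- lc_grid(t0, t_max, config$a0 %||% 0L, config$a_max %||% 100L, sx)
    inputs <- config$inputs[[sx]] %||%
      .inputs_from_data(obs, grid, init_counts[[sx]])
    blocks <- block_structure(grid, age_edges = config$age_edges %||% list(),
                              time_edges = config$time_edges,
                              time_block_width = config$time_block_width %||% 1)
    fit <- fit_mle(obs, config$fixed[[sx]] %||% default_hazard_ratios(sx),
                   blocks, inputs, control = config$control %||% list())
    say("fitted %s: %d parameters, loglik %.4f, convergence %d",
        sx, length(fit$theta_hat), fit$loglik, fit$convergence)
    fits[[sx]] <- fit
    fc <- project_burden(fit, horizon_end = horizon_end,
                         age_groups = age_groups, n_boot = n_boot,
                         seed = seed + i)
    forecasts[[sx]] <- fc
    say("projected %s to %d%s", sx, horizon_end,
        if (n_boot > 0) sprintf(" with %d bootstrap replicates (seed %d)",
                                n_boot, seed + i) else "")
    peaks <- lapply(c(cases = "cases", deaths = "deaths"), function(out) {
      pk <- peak_summary(fc, out, "all")
      list(year = pk$peak_year, value = pk$peak_value,
           value_ci = pk$value_ci, year_ci = pk$year_ci, flags = pk$flags)
    })
    sens <- sensitivity_ks(fit, multipliers = multipliers,
                           horizon_end = horizon_end,
                           age_groups = age_groups)
    sensitivities[[sx]] <- sens
    report$sexes[[sx]] <- list(
      n_params = length(fit$theta_hat), loglik = fit$loglik,
      convergence = fit$convergence, psd_repaired = fit$psd_repaired,
      peaks = peaks)
  }
  forecast_tab <- do.call(rbind, forecasts)
  sens_tab <- do.call(rbind, sensitivities)
  rownames(forecast_tab) <- rownames(sens_tab) <- NULL

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (sx in names(fits))
      write_fit_json(fits[[sx]], file.path(config$out_dir,
                                           sprintf("fit_%s.json", sx)))
    write.csv(forecast_tab, file.path(config$out_dir, "forecast.csv"),
              row.names = FALSE)
    write.csv(sens_tab, file.path(config$out_dir, "sensitivity.csv"),
              row.names = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    resolved <- config[!vapply(config, is.object, logical(1))]
    resolved <- resolved[vapply(resolved, function(x)
      is.numeric(x) || is.character(x) || is.logical(x) || is.list(x),
      logical(1))]
    resolved$obs <- NULL; resolved$inputs <- NULL
    resolved$seed <- seed; resolved$t0 <- t0; resolved$t_max <- t_max
    resolved$horizon_end <- horizon_end
    yaml::write_yaml(resolved, file.path(config$out_dir, "config.yaml"))
    writeLines(log_lines, file.path(config$out_dir, "run.log"))
  }
  report$forecast <- forecast_tab
  report$sensitivity <- sens_tab
  report$fits <- fits
  report$log <- log_lines
  invisible(report)
}

# inputs built from the data: inflow = observed population at the youngest
# modelled age; initial state supplied by the user (or an initial-states file)
.inputs_from_data <- function(obs, grid, init_counts) {
  if (is.null(init_counts))
    stop(sprintf("no initial state available for %s: supply `inputs` or `initial_states`",
                 grid$sex), call. = FALSE)
  pop <- obs$population
  pop <- pop[pop$sex == grid$sex & pop$age_lo == grid$a0, , drop = FALSE]
  years <- (grid$t0 + 1L):grid$t_max
  inflow <- setNames(pop$count[match(years, pop$year)], years)
  if (anyNA(inflow))
    stop("population table does not cover the fitting years at the youngest age",
         call. = FALSE)
  model_inputs(population_state(grid$t0, init_counts, grid), inflow)
}
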