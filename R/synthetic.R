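#' Synthetic scenario configuration
#'
#' Describes a complete data-generating world with known ground truth:
#' grid, per-sex rate surfaces (as `function(year, age)` families or
#' `lc_rates` matrices), fixed hazard ratios, a yearly birth series, the
#' effective binomial sample size of the smoking survey, and the strata on
#' which observations are reported. [generate_observations()] turns a
#' scenario into noisy observed tables plus the noiseless truth, so every
#' stage of the pipeline can be tested against known rates.
#'
#' @param t0 first observed calendar year.
#' @param t_max last observed calendar year (the learning-data cutoff).
#' @param horizon_end last forecast year the scenario must support.
#' @param a0,a_max age range (closed top bin at `a_max`).
#' @param sexes named list (`male`, `female`, or one of them); each element
#'   a list with `hr` (an [hazard_ratios()]) and `rates` (named list of the
#'   five surfaces as functions, scalars, or an `lc_rates` object).
#' @param births function of calendar year giving the number of age-`a0`
#'   entrants (used both for the pre-`t0` cohorts of the initial state and
#'   for the yearly inflow), or a single number.
#' @param n_eff effective binomial sample size per prevalence stratum
#'   (default 1000).
#' @param count_age_width width in years of the age groups of the count
#'   tables (default 5).
#' @param count_age_cap lower bound of the open top age group of the count
#'   tables (default 85, i.e. `85+`).
#' @param prevalence_breaks ascending age breaks of the survey strata
#'   (default `c(20, 30, 40, 50, 60, Inf)`, i.e. 10-year groups 20-59 and
#'   `60+`).
#' @param seed mandatory integer seed for the observation noise.
#' @return An object of class `lc_scenario`.
#' @export
lc_scenario <- function(t0, t_max, horizon_end, a0 = 0, a_max = 100,
                        sexes, births, n_eff = 1000,
                        count_age_width = 5, count_age_cap = 85,
                        prevalence_breaks = c(20, 30, 40, 50, 60, Inf),
                        seed) {
  if (missing(seed) || is.null(seed))
    stop("a `seed` is mandatory in a scenario", call. = FALSE)
  if (!(t0 < t_max && t_max <= horizon_end))
    stop("need t0 < t_max <= horizon_end", call. = FALSE)
  if (!length(sexes) || is.null(names(sexes)) ||
      !all(names(sexes) %in% c("male", "female")))
    stop("`sexes` must be a named list with elements `male` and/or `female`",
         call. = FALSE)
  for (sx in names(sexes)) {
    el <- sexes[[sx]]
    if (is.null(el$hr) || is.null(el$rates))
      stop(sprintf("`sexes$%s` needs elements `hr` and `rates`", sx),
           call. = FALSE)
    .check_hr(el$hr)
  }
  if (is.numeric(births) && length(births) == 1L) {
    b0 <- births
    births <- function(year) rep(b0, length(year))
  }
  if (!is.function(births))
    stop("`births` must be a function of year or a single number",
         call. = FALSE)
  structure(list(t0 = as.integer(t0), t_max = as.integer(t_max),
                 horizon_end = as.integer(horizon_end),
                 a0 = as.integer(a0), a_max = as.integer(a_max),
                 sexes = sexes, births = births, n_eff = n_eff,
                 count_age_width = count_age_width,
                 count_age_cap = count_age_cap,
                 prevalence_breaks = prevalence_breaks,
                 seed = as.integer(seed)),
            class = "lc_scenario")
}

#' @export
print.lc_scenario <- function(x, ...) {
  cat(sprintf("<lc_scenario> years %d-%d (horizon %d), ages %d-%d, sexes: %s, seed %d\n",
              x$t0, x$t_max, x$horizon_end, x$a0, x$a_max,
              paste(names(x$sexes), collapse = ", "), x$seed))
  invisible(x)
}

#' A Japan-like default scenario
#'
#' A documented scenario emulating the qualitative structure of the
#' Japanese data: male smoking uptake high in the 1960s (adult prevalence
#' above 0.7) and declining steeply over calendar time, much lower female
#' uptake with a milder decline, cessation rising with age and over time,
#' Gompertz background mortality with slow secular improvement,
#' never-smoker lung cancer hazard rising steeply after age 40 with a
#' calendar trend, a roughly constant excess case fatality, and a birth
#' series with a baby-boom-like bulge followed by fertility decline. The
#' fixed hazard ratios are the literature values of
#' [default_hazard_ratios()]. Under these defaults the absolute number of
#' cases peaks strictly inside the forecast horizon while ageing keeps
#' some per-100,000 rates rising.
#'
#' @param t0,t_max,horizon_end scenario years (defaults 1965, 2014, 2050).
#' @param n_eff,seed see [lc_scenario()].
#' @return An `lc_scenario`.
#' @export
japan_like_scenario <- function(t0 = 1965, t_max = 2014, horizon_end = 2065,
                                n_eff = 1000, seed = 20190308) {
  male <- list(
    hr = default_hazard_ratios("male"),
    rates = list(
      sigma = function(t, a)
        0.21 * exp(-0.5 * ((a - 22) / 6)^2) *
          (0.15 + 0.85 * stats::plogis((1985 - t) / 11)),
      delta = function(t, a)
        (0.005 + 0.04 * stats::plogis((a - 60) / 8)) *
          (1 + 1.5 * stats::plogis((t - 1995) / 10)),
      lambda = function(t, a)
        1.2e-5 * exp(0.105 * pmax(a - 40, 0)) *
          (0.6 + 0.8 * stats::plogis((t - 1990) / 12)),
      mu = function(t, a)
        4e-5 * exp(0.088 * a) * exp(-0.004 * (t - 1970)),
      nu = function(t, a)
        0.28 * exp(-0.004 * (t - 1970)) + 0 * a
    )
  )
  female <- list(
    hr = default_hazard_ratios("female"),
    rates = list(
      sigma = function(t, a)
        0.018 * exp(-0.5 * ((a - 23) / 6)^2) *
          (0.6 + 0.4 * stats::plogis((2000 - t) / 15)),
      delta = function(t, a)
        (0.010 + 0.040 * stats::plogis((a - 55) / 8)) *
          (1 + 0.8 * stats::plogis((t - 1995) / 10)),
      lambda = function(t, a)
        0.9e-5 * exp(0.100 * pmax(a - 40, 0)) *
          (0.6 + 0.8 * stats::plogis((t - 1990) / 12)),
      mu = function(t, a)
        2.5e-5 * exp(0.088 * a) * exp(-0.004 * (t - 1970)),
      nu = function(t, a)
        0.26 * exp(-0.004 * (t - 1970)) + 0 * a
    )
  )
  # birth series shaped like Japan's: a large post-war baby boom (1949), an
  # echo boom (1973), and a long fertility decline; pre-t0 values size the
  # initial age profile's cohorts
  births <- function(year)
    6000 + 9000 * stats::plogis((1985 - year) / 20) +
      8000 * exp(-0.5 * ((year - 1949) / 5)^2) +
      5000 * exp(-0.5 * ((year - 1973) / 5)^2)
  lc_scenario(t0, t_max, horizon_end,
              sexes = list(male = male, female = female),
              births = births, n_eff = n_eff, seed = seed)
}

#' Block-constant scenario with explicit ground-truth parameters
#'
#' Builds a single-sex scenario whose true rate surfaces are exactly
#' [expand_rates()]`(theta, blocks)` carried forward over the horizon, so
#' maximum-likelihood recovery of `theta` can be checked block by block.
#'
#' @param blocks an [block_structure()] on the fitting grid.
#' @param theta true log-rate vector on `blocks`.
#' @param hr fixed hazard ratios; default literature values for the
#'   grid's sex.
#' @param births see [lc_scenario()]; default constant 5000.
#' @param horizon_end last forecast year; default 15 years past the fit.
#' @param ... passed to [lc_scenario()] (`n_eff`, strata settings, `seed`).
#' @return An `lc_scenario`.
#' @export
blockwise_scenario <- function(blocks, theta, hr = NULL, births = 5000,
                               horizon_end = NULL, ...) {
  blocks <- .check_blocks(blocks)
  g <- blocks$grid
  rates <- expand_rates(theta, blocks)
  hr <- hr %||% default_hazard_ratios(g$sex)
  horizon_end <- horizon_end %||% (g$t_max + 15L)
  sexes <- setNames(list(list(hr = hr, rates = rates)), g$sex)
  lc_scenario(g$t0, g$t_max, horizon_end, a0 = g$a0, a_max = g$a_max,
              sexes = sexes, births = births, ...)
}

#' Generate a synthetic observation set
#'
#' Simulates the scenario's ground-truth model and draws the observed
#' tables around the deterministic expectations: Poisson noise on the four
#' count tables and binomial sampling (size `n_eff`) on the smoking
#' prevalence strata. With `noise = FALSE` the tables carry the
#' expectations themselves (and prevalence numerators `p * n_eff`), which
#' is the noiseless oracle used by recovery tests. Runs are reproducible:
#' the same scenario and seed give identical output.
#'
#' The initial population state at `t0` is constructed by marching each
#' pre-`t0` birth cohort (of size `births(t0 - age)`) through the age
#' profile of the year-`t0` rates; the projected-population table over the
#' forecast horizon is the model's own noiseless population.
#'
#' @param scenario an [lc_scenario()].
#' @param noise draw observation noise (default `TRUE`).
#' @param seed overrides the scenario seed when given.
#' @return A list of class `lc_synth`: `observations` (an
#'   [observation_set()] combining all sexes), and `truth`, a per-sex list
#'   with the full-horizon `rates`, `hr`, fitting `inputs`
#'   ([model_inputs()] on the `t0:t_max` grid) and the noiseless
#'   `trajectory` over the full horizon.
#' @export
generate_observations <- function(scenario, noise = TRUE, seed = NULL) {
  if (!inherits(scenario, "lc_scenario"))
    stop("`scenario` must be an `lc_scenario`", call. = FALSE)
  set.seed(as.integer(seed %||% scenario$seed))
  per_sex <- lapply(names(scenario$sexes), function(sx)
    .generate_one_sex(scenario, sx, noise))
  names(per_sex) <- names(scenario$sexes)
  bind <- function(nm) do.call(rbind, lapply(per_sex, function(x) x$tables[[nm]]))
  obs <- observation_set(
    incidence = bind("incidence"), deaths = bind("deaths"),
    prevalence = bind("prevalence"), population = bind("population"),
    other_deaths = bind("other_deaths"),
    projected_population = bind("projected_population")
  )
  structure(list(observations = obs,
                 truth = lapply(per_sex, function(x) x$truth),
                 scenario = scenario),
            class = "lc_synth")
}

.generate_one_sex <- function(scenario, sx, noise) {
  el <- scenario$sexes[[sx]]
  sim_end <- scenario$horizon_end + 1L
  full_grid <- lc_grid(scenario$t0, sim_end, scenario$a0, scenario$a_max, sx)
  rates <- if (inherits(el$rates, "lc_rates")) {
    rg <- attr(el$rates, "grid")
    extend_forecast(el$rates, rg$t_max, sim_end)
  } else {
    do.call(rate_surfaces, c(list(full_grid), el$rates))
  }
  ages <- grid_ages(full_grid)
  init_counts <- .initial_profile(rates, el$hr, full_grid, scenario$births)
  inflow_years <- (scenario$t0 + 1L):sim_end
  inflow <- setNames(scenario$births(inflow_years), inflow_years)
  init <- population_state(scenario$t0, init_counts, full_grid)
  traj <- simulate_population(rates, el$hr, init, inflow)

  templates <- .strata_templates(scenario, sx)
  mu <- expected_observations(traj, templates)
  tables <- templates
  for (nm in .count_tables)
    tables[[nm]]$count <- if (noise) rpois(length(mu[[nm]]), mu[[nm]])
                          else mu[[nm]]
  tables$prevalence$denominator <- rep(scenario$n_eff,
                                       nrow(tables$prevalence))
  tables$prevalence$numerator <- if (noise)
    rbinom(length(mu$prevalence), scenario$n_eff, mu$prevalence)
  else mu$prevalence * scenario$n_eff
  # exogenous projection = the model's own noiseless future population
  proj_years <- (scenario$t_max + 1L):scenario$horizon_end
  proj <- .single_age_template(proj_years, ages, sx)
  proj$count <- .stratum_sums(apply(traj$states, c(2, 3), sum), proj,
                              full_grid, full_grid$t0, full_grid$t_max,
                              "projected_population")
  tables$projected_population <- proj

  fit_grid <- lc_grid(scenario$t0, scenario$t_max, scenario$a0,
                      scenario$a_max, sx)
  fit_init <- population_state(scenario$t0, init_counts, fit_grid)
  fit_inflow <- inflow[as.character((scenario$t0 + 1L):scenario$t_max)]
  list(tables = tables,
       truth = list(rates = rates, hr = el$hr,
                    inputs = model_inputs(fit_init, fit_inflow),
                    trajectory = traj))
}

# Age profile at t0: each pre-t0 cohort (born in year t0 - age, of size
# births(t0 - age)) is marched through the year-t0 rate column up to its
# current age. The closed top bin additionally accumulates the survivors
# of all cohorts older than a_max, so constant conditions start exactly at
# their stationary profile.
.initial_profile <- function(rates, hr, grid, births) {
  ages <- grid_ages(grid)
  n <- length(ages)
  r0 <- .rates_at_year(rates, grid$t0)
  unit <- matrix(0, 4, n)
  unit[1, 1] <- 1
  for (j in seq_len(n - 1L)) {
    gen <- cell_generator(vapply(r0, `[[`, numeric(1), j), hr,
                          year = grid$t0, age = ages[j])
    unit[, j + 1L] <- advance_cell(unit[, j], gen)$state
  }
  out <- sweep(unit, 2, births(grid$t0 - (ages - grid$a0)), `*`)
  # survivors above the top age keep experiencing the oldest cell's rates;
  # with the tail cohorts' birth size held at its oldest value the pool is
  # the geometric sum P (I - P)^-1 applied to the age-a_max survivors
  gen_top <- cell_generator(vapply(r0, `[[`, numeric(1), n), hr,
                            year = grid$t0, age = ages[n])
  P <- .expm_cpp(.augment_generator(gen_top))[1:4, 1:4]
  b_tail <- births(grid$t0 - (grid$a_max - grid$a0) - 1L)
  pool <- tryCatch(solve(diag(4) - P, P %*% unit[, n]),
                   error = function(e)
                     stop("top-age mortality too small to close the age ",
                          "distribution; increase `mu` at the oldest ages",
                          call. = FALSE))
  out[, n] <- out[, n] + b_tail * pmax(as.numeric(pool), 0)
  out
}

.strata_templates <- function(scenario, sx) {
  # a year's flows are the events of [t, t + 1), so the last flow stratum
  # supported by the fitting grid t0..t_max is year t_max - 1; the Jan-1
  # state tables (population, prevalence) cover every grid year
  flow_years <- scenario$t0:(scenario$t_max - 1L)
  obs_years <- scenario$t0:scenario$t_max
  ages <- scenario$a0:scenario$a_max
  cap <- min(scenario$count_age_cap, scenario$a_max)
  lo <- seq(scenario$a0, cap, by = scenario$count_age_width)
  hi <- c(lo[-1L], Inf)
  count_tab <- expand.grid(year = flow_years, i = seq_along(lo))
  count_tab <- data.frame(sex = sx, year = count_tab$year,
                          age_lo = lo[count_tab$i], age_hi = hi[count_tab$i])
  pb <- scenario$prevalence_breaks
  pb <- pb[pb <= scenario$a_max | is.infinite(pb)]
  if (length(pb) < 2L) pb <- c(scenario$a0, Inf)
  plo <- pb[-length(pb)]; phi <- pb[-1L]
  prev_tab <- expand.grid(year = obs_years, i = seq_along(plo))
  prev_tab <- data.frame(sex = sx, year = prev_tab$year,
                         age_lo = plo[prev_tab$i], age_hi = phi[prev_tab$i])
  list(incidence = count_tab, deaths = count_tab,
       other_deaths = count_tab,
       population = .single_age_template(obs_years, ages, sx),
       prevalence = prev_tab)
}

.single_age_template <- function(years, ages, sx) {
  tab <- expand.grid(year = years, age_lo = ages)
  data.frame(sex = sx, year = tab$year, age_lo = tab$age_lo,
             age_hi = tab$age_lo + 1)
}
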