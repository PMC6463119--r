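#' Exogenous model inputs for one sex
#'
#' The simulation needs, besides the rate surfaces: the initial population
#' state at the first grid year and the yearly boundary inflow of age-`a0`
#' entrants (all never-smokers). Both are treated as known inputs, not
#' estimated: the inflow comes from population data (census counts at
#' `a0`, or the official projection over the forecast horizon).
#'
#' @param initial_state an [population_state()] at the grid's first year.
#' @param inflow named numeric vector of entrants per calendar year
#'   (covering `t0 + 1, ..., t_max`), or a single number.
#' @return An object of class `lc_inputs`.
#' @export
model_inputs <- function(initial_state, inflow) {
  if (!inherits(initial_state, "lc_state"))
    stop("`initial_state` must be an `lc_state`", call. = FALSE)
  structure(list(grid = initial_state$grid, initial_state = initial_state,
                 inflow = inflow),
            class = "lc_inputs")
}

# Poisson log-pmf valid for real-valued k >= 0 (noiseless data carry the
# expectations themselves); exact for integer k
.pois_lpmf <- function(k, mean) {
  out <- ifelse(k == 0, 0, -Inf)          # mean == 0 branch
  pos <- mean > 0
  out[pos] <- k[pos] * log(mean[pos]) - mean[pos] - lgamma(k[pos] + 1)
  out
}

# binomial log-pmf, real-valued k permitted
.binom_lpmf <- function(k, n, p) {
  out <- numeric(length(k))
  out[] <- -Inf
  edge0 <- p <= 0
  edge1 <- p >= 1
  out[edge0] <- ifelse(k[edge0] == 0, 0, -Inf)
  out[edge1] <- ifelse(k[edge1] == n[edge1], 0, -Inf)
  mid <- !edge0 & !edge1
  out[mid] <- lgamma(n[mid] + 1) - lgamma(k[mid] + 1) -
    lgamma(n[mid] - k[mid] + 1) + k[mid] * log(p[mid]) +
    (n[mid] - k[mid]) * log1p(-p[mid])
  out
}

#' Composite log-likelihood of the observed tables
#'
#' The observation model treats the four count tables (lung cancer
#' incidence, lung cancer deaths, other-cause deaths, population size) as
#' independent Poisson observations of the model's expected counts, and the
#' surveyed current-smoker prevalence as binomial sampling with the
#' surveyed denominator and model proportion `S / (M + S + E + L)`. The
#' log-likelihood is the sum of the exact log probability masses over all
#' strata; a zero model mean facing a positive count yields `-Inf` (not an
#' exception).
#'
#' @param theta log-rate parameter vector on the block structure.
#' @param obs an [observation_set()].
#' @param fixed an [hazard_ratios()] object (held fixed, outside `theta`).
#' @param blocks an [block_structure()].
#' @param inputs an [model_inputs()] object.
#' @return Scalar log-likelihood (possibly `-Inf`).
#' @export
log_likelihood <- function(theta, obs, fixed, blocks, inputs) {
  blocks <- .check_blocks(blocks)
  if (!inherits(inputs, "lc_inputs"))
    stop("`inputs` must come from `model_inputs()`", call. = FALSE)
  rates <- expand_rates(theta, blocks)
  traj <- simulate_population(rates, fixed, inputs$initial_state,
                              inputs$inflow)
  .loglik_from_traj(traj, obs)
}

# Precompute stratum index structures so repeated likelihood evaluations
# (optimizer, Hessian, bootstrap) skip the data-frame bookkeeping.
.precompute_strata <- function(obs, grid) {
  sex <- grid$sex
  flow_tab <- function(nm, first_year, last_year) {
    tab <- obs[[nm]]
    tab <- tab[tab$sex == sex, , drop = FALSE]
    if (!nrow(tab)) return(NULL)
    if (any(tab$year < first_year | tab$year > last_year))
      stop(sprintf("`%s` strata refer to years outside %d-%d", nm,
                   first_year, last_year), call. = FALSE)
    if (any(tab$age_lo < grid$a0 | tab$age_lo > grid$a_max |
              tab$age_hi <= grid$a0))
      stop(sprintf("`%s` strata refer to ages outside the grid", nm),
           call. = FALSE)
    t_idx <- tab$year - first_year + 1L
    lo_i <- pmax(tab$age_lo, grid$a0) - grid$a0 + 1L
    hi_i <- pmin(tab$age_hi - 1, grid$a_max) - grid$a0 + 1L
    list(hi = cbind(hi_i + 1L, t_idx), lo = cbind(lo_i, t_idx),
         k = tab$count, num = tab$numerator, den = tab$denominator)
  }
  list(incidence = flow_tab("incidence", grid$t0, grid$t_max - 1L),
       deaths = flow_tab("deaths", grid$t0, grid$t_max - 1L),
       other_deaths = flow_tab("other_deaths", grid$t0, grid$t_max - 1L),
       population = flow_tab("population", grid$t0, grid$t_max),
       prevalence = flow_tab("prevalence", grid$t0, grid$t_max))
}

.indexed_sums <- function(values, pre) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  cs <- rbind(0, apply(values, 2, cumsum))
  cs[pre$hi] - cs[pre$lo]
}

.loglik_indexed <- function(traj, pre) {
  ll <- 0
  flow_of <- c(incidence = "new_cases", deaths = "cancer_deaths",
               other_deaths = "other_deaths")
  for (nm in names(flow_of)) {
    p <- pre[[nm]]
    if (is.null(p)) next
    ll <- ll + sum(.pois_lpmf(p$k, .indexed_sums(traj$flows[flow_of[[nm]], , ],
                                                 p)))
  }
  pop_tot <- colSums(traj$states)
  if (!is.null(pre$population))
    ll <- ll + sum(.pois_lpmf(pre$population$k,
                              .indexed_sums(pop_tot, pre$population)))
  p <- pre$prevalence
  if (!is.null(p)) {
    den <- .indexed_sums(pop_tot, p)
    prop <- ifelse(den > 0, .indexed_sums(traj$states["S", , ], p) / den, 0)
    ll <- ll + sum(.binom_lpmf(p$num, p$den, prop))
  }
  ll
}

.loglik_from_traj <- function(traj, obs) {
  mu <- expected_observations(traj, obs)
  sex <- traj$grid$sex
  ll <- 0
  for (nm in .count_tables) {
    tab <- obs[[nm]]
    tab <- tab[tab$sex == sex, , drop = FALSE]
    if (!nrow(tab)) next
    ll <- ll + sum(.pois_lpmf(tab$count, mu[[nm]]))
  }
  tab <- obs$prevalence
  tab <- tab[tab$sex == sex, , drop = FALSE]
  if (nrow(tab))
    ll <- ll + sum(.binom_lpmf(tab$numerator, tab$denominator,
                               mu$prevalence))
  ll
}
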