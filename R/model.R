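#' Population state at one calendar year
#'
#' Counts of never-smokers (M), current smokers (S), ex-smokers (E) and
#' living lung-cancer patients (L) by single year of age, for one sex, at
#' the start (Jan 1) of one calendar year.
#'
#' @param year calendar year the state refers to.
#' @param counts a `4 x n_ages` matrix with rows `M`, `S`, `E`, `L` and one
#'   column per age `a0:a_max`; all entries finite and nonnegative.
#' @param grid the [lc_grid()] the state lives on.
#' @return An object of class `lc_state`.
#' @export
population_state <- function(year, counts, grid) {
  grid <- .check_grid(grid)
  ages <- grid_ages(grid)
  if (!is.matrix(counts) || nrow(counts) != 4L || ncol(counts) != length(ages))
    stop(sprintf("`counts` must be a 4 x %d matrix (M, S, E, L by age)",
                 length(ages)), call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("compartment counts must be finite and nonnegative", call. = FALSE)
  dimnames(counts) <- list(compartment = .compartments, age = ages)
  structure(list(year = as.integer(year), counts = counts, grid = grid),
            class = "lc_state")
}

#' @export
print.lc_state <- function(x, ...) {
  tot <- rowSums(x$counts)
  cat(sprintf("<lc_state> %s, year %d: M=%.4g S=%.4g E=%.4g L=%.4g (total %.6g)\n",
              x$grid$sex, x$year, tot[1], tot[2], tot[3], tot[4], sum(tot)))
  invisible(x)
}

#' Within-cell generator of the compartmental flow
#'
#' Builds the 4x4 generator of the linear system governing (M, S, E, L)
#' inside one (year, age) cell with frozen rates, together with the
#' absorbing outflow rates (other-cause death per compartment, and the
#' excess cancer death rate acting on L). Never-smokers leave M by uptake
#' `sigma`, cancer onset `lambda` and death `mu`; smokers leave S by
#' cessation `delta`, onset `kS * lambda` and death `(1 + qS) * mu`;
#' ex-smokers leave E by onset `kE * lambda` and death `(1 + qE) * mu`;
#' patients leave L by death `mu + nu`. Off-diagonal entries are the
#' between-compartment fluxes, and each column sums to minus that
#' compartment's total death rate, so the generator conserves persons up to
#' deaths.
#'
#' @param rates named numeric vector with elements `sigma`, `delta`,
#'   `lambda`, `mu`, `nu` (per person-year).
#' @param hr an [hazard_ratios()] object.
#' @param year,age optional cell labels used in error messages.
#' @return A list of class `lc_generator`: `G` (4x4 matrix), `other_death`
#'   (length-4 vector of other-cause death rates), `cancer_death`
#'   (length-4 vector, nonzero only for L) and `case_inflow` (length-4
#'   vector of cancer-onset rates out of M, S, E).
#' @export
cell_generator <- function(rates, hr, year = NULL, age = NULL) {
  hr <- .check_hr(hr)
  r <- rates[.rate_symbols]
  bad <- .rate_symbols[!is.finite(unlist(r)) | unlist(r) < 0]
  if (length(bad)) {
    where <- if (!is.null(year) || !is.null(age))
      sprintf(" at cell (year %s, age %s)",
              year %||% "?", age %||% "?") else ""
    stop(sprintf("invalid (negative or non-finite) rate `%s`%s",
                 bad[[1L]], where), call. = FALSE)
  }
  sigma <- r[["sigma"]]; delta <- r[["delta"]]; lambda <- r[["lambda"]]
  mu <- r[["mu"]]; nu <- r[["nu"]]
  onset <- c(lambda, hr$kS * lambda, hr$kE * lambda, 0)
  other <- c(mu, (1 + hr$qS) * mu, (1 + hr$qE) * mu, mu)
  G <- matrix(0, 4, 4, dimnames = list(.compartments, .compartments))
  G[1, 1] <- -(mu + sigma + lambda)
  G[2, 1] <- sigma
  G[2, 2] <- -((1 + hr$qS) * mu + delta + hr$kS * lambda)
  G[3, 2] <- delta
  G[3, 3] <- -((1 + hr$qE) * mu + hr$kE * lambda)
  G[4, 4] <- -(mu + nu)
  G[4, 1:3] <- onset[1:3]
  names(other) <- names(onset) <- .compartments
  structure(list(G = G, other_death = other,
                 cancer_death = c(M = 0, S = 0, E = 0, L = nu),
                 case_inflow = onset),
            class = "lc_generator")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 7x7 augmented generator: compartments + death/case accumulators
.augment_generator <- function(gen) {
  A <- matrix(0, 7, 7)
  A[1:4, 1:4] <- gen$G
  A[5, 1:4] <- gen$other_death
  A[6, 1:4] <- gen$cancer_death
  A[7, 1:4] <- gen$case_inflow
  A
}

#' Advance one cohort through one cell
#'
#' Solves the frozen-rate linear system exactly over a step of `dt` years
#' via the matrix exponential of the augmented generator, returning the
#' state at cell exit and the expected flows (incident cases, cancer
#' deaths, other-cause deaths) that occurred inside the cell. Persons are
#' conserved: entering persons equal exiting persons plus deaths.
#'
#' @param state numeric length-4 vector (M, S, E, L) at cell entry.
#' @param gen an `lc_generator` from [cell_generator()].
#' @param dt step length in years (default 1, the grid step).
#' @return A list with `state` (length-4, cell exit) and `flows` (named
#'   length-3: `new_cases`, `cancer_deaths`, `other_deaths`).
#' @export
advance_cell <- function(state, gen, dt = 1) {
  if (!inherits(gen, "lc_generator"))
    stop("`gen` must come from `cell_generator()`", call. = FALSE)
  if (length(state) != 4L || any(!is.finite(state)) || any(state < 0))
    stop("`state` must be 4 nonnegative counts (M, S, E, L)", call. = FALSE)
  P <- .expm_cpp(.augment_generator(gen) * dt)
  out <- as.numeric(P %*% c(state, 0, 0, 0))
  list(state = setNames(out[1:4], .compartments),
       flows = c(new_cases = out[7], cancer_deaths = out[6],
                 other_deaths = out[5]))
}

#' Advance the whole population state by one year
#'
#' Every cohort ages by exactly one year along its characteristic: the
#' cohort at age `a` in year `t` is advanced through cell `(t, a)` and
#' lands at age `a + 1` in year `t + 1`. The cohort leaving the closed top
#' bin `a_max` is retained there (it keeps experiencing the oldest cell's
#' rates), and the new age-`a0` cohort consists of `inflow` never-smokers.
#'
#' @param state an [population_state()] for year `t`.
#' @param rates an `lc_rates` object defining cell rates for year `t`.
#' @param hr an [hazard_ratios()] object.
#' @param inflow number of persons entering at age `a0` in year `t + 1`
#'   (all never-smokers).
#' @return A list with `state` (the `lc_state` at `t + 1`) and `flows`
#'   (a `3 x n_ages` matrix of expected `new_cases`, `cancer_deaths`,
#'   `other_deaths` occurring during year `t`, indexed by age at the start
#'   of the year).
#' @export
advance_year <- function(state, rates, hr, inflow) {
  if (!inherits(state, "lc_state"))
    stop("`state` must be an `lc_state`", call. = FALSE)
  rates <- .check_rates(rates)
  hr <- .check_hr(hr)
  g <- state$grid
  if (!is.finite(inflow) || inflow < 0)
    stop("`inflow` must be a nonnegative count", call. = FALSE)
  rr <- .rates_at_year(rates, state$year)
  out <- .advance_cohorts_cpp(state$counts, rr$sigma, rr$delta, rr$lambda,
                              rr$mu, rr$nu, hr$kS, hr$kE, hr$qS, hr$qE, 1.0)
  n <- ncol(state$counts)
  new_counts <- matrix(0, 4, n)
  # age everyone by one year; the top bin is closed
  new_counts[, 2:n] <- out[1:4, 1:(n - 1)]
  new_counts[, n] <- new_counts[, n] + out[1:4, n]
  new_counts[1, 1] <- inflow
  # numerical floor: the exponential step is nonnegative up to roundoff
  new_counts[new_counts < 0] <- 0
  flows <- out[c(7, 6, 5), , drop = FALSE]
  dimnames(flows) <- list(flow = .flow_labels, age = grid_ages(g))
  list(state = population_state(state$year + 1L, new_counts, g),
       flows = flows)
}

#' Deterministic simulation of the population over the grid
#'
#' Runs [advance_year()] from the initial state at `t0` through the last
#' grid year, recording the population state at every year and the expected
#' event flows of every (year, age) cell. The simulation is deterministic:
#' repeated calls give identical trajectories.
#'
#' @param rates an `lc_rates` object covering every simulated year (rates
#'   for the final grid year are not needed since no step starts there).
#' @param hr an [hazard_ratios()] object.
#' @param initial_state an [population_state()] at the grid's `t0`.
#' @param inflow named numeric vector of age-`a0` entrants for years
#'   `t0 + 1, ..., t_max` (names are years), or a single number recycled.
#' @return An object of class `lc_trajectory`: a list with `states`
#'   (`4 x n_ages x n_years` array), `flows` (`3 x n_ages x (n_years - 1)`
#'   array; flows of year `t` are those occurring during `[t, t + 1)`),
#'   and the grid.
#' @export
simulate_population <- function(rates, hr, initial_state, inflow) {
  rates <- .check_rates(rates)
  hr <- .check_hr(hr)
  if (!inherits(initial_state, "lc_state"))
    stop("`initial_state` must be an `lc_state`", call. = FALSE)
  g <- initial_state$grid
  years <- grid_years(g)
  ages <- grid_ages(g)
  if (initial_state$year != g$t0)
    stop("`initial_state` must be at the grid's first year", call. = FALSE)
  step_years <- years[-length(years)]
  inflow <- .resolve_inflow(inflow, step_years + 1L)

  states <- array(0, dim = c(4, length(ages), length(years)),
                  dimnames = list(compartment = .compartments, age = ages,
                                  year = years))
  flows <- array(0, dim = c(3, length(ages), length(step_years)),
                 dimnames = list(flow = .flow_labels, age = ages,
                                 year = step_years))
  # inlined year loop (equivalent to repeated advance_year(); kept lean
  # because the optimizer calls this thousands of times)
  rg <- attr(rates, "grid")
  if (rg$t0 > g$t0 || rg$t_max < g$t_max - 1L || rg$a0 != g$a0 ||
      rg$a_max != g$a_max)
    stop("rate surfaces do not cover the simulation grid", call. = FALSE)
  n <- length(ages)
  counts <- initial_state$counts
  states[, , 1L] <- counts
  for (i in seq_along(step_years)) {
    ri <- step_years[i] - rg$t0 + 1L
    out <- .advance_cohorts_cpp(counts, rates$sigma[ri, ], rates$delta[ri, ],
                                rates$lambda[ri, ], rates$mu[ri, ],
                                rates$nu[ri, ], hr$kS, hr$kE, hr$qS, hr$qE,
                                1.0)
    nxt <- matrix(0, 4, n)
    nxt[, 2:n] <- out[1:4, 1:(n - 1L)]
    nxt[, n] <- nxt[, n] + out[1:4, n]
    nxt[1, 1] <- inflow[[i]]
    nxt[nxt < 0] <- 0
    counts <- nxt
    states[, , i + 1L] <- counts
    flows[, , i] <- out[c(7, 6, 5), ]
  }
  structure(list(states = states, flows = flows, grid = g),
            class = "lc_trajectory")
}

.resolve_inflow <- function(inflow, years_needed) {
  if (length(inflow) == 1L && is.null(names(inflow)))
    return(rep(as.numeric(inflow), length(years_needed)))
  if (is.null(names(inflow)))
    stop("`inflow` must be named by calendar year (or be a single number)",
         call. = FALSE)
  missing <- setdiff(as.character(years_needed), names(inflow))
  if (length(missing))
    stop(sprintf("inflow missing for years: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  v <- as.numeric(inflow[as.character(years_needed)])
  if (any(!is.finite(v)) || any(v < 0))
    stop("inflow values must be finite and nonnegative", call. = FALSE)
  v
}

#' @export
print.lc_trajectory <- function(x, ...) {
  g <- x$grid
  cat(sprintf("<lc_trajectory> %s, years %d-%d, ages %d-%d\n",
              g$sex, g$t0, g$t_max, g$a0, g$a_max))
  cat(sprintf("  final population %.6g; total simulated new cases %.6g\n",
              sum(x$states[, , dim(x$states)[3]]), sum(x$flows["new_cases", , ])))
  invisible(x)
}
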