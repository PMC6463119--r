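#' Expected observations from a simulated trajectory
#'
#' Maps a deterministic trajectory onto the strata of an observation set:
#' expected incidence / cancer-death / other-cause-death counts are sums of
#' the corresponding cell flows over the member ages of each stratum,
#' expected population counts are sums of `M + S + E + L` at the Jan-1
#' state, and expected current-smoker prevalence is
#' `sum(S) / sum(M + S + E + L)` over the stratum's ages.
#'
#' Flow strata must refer to years `t0, ..., t_max - 1` (a year's flows are
#' the events of `[t, t + 1)`); state strata may use any grid year.
#' Strata referencing years or ages outside the grid raise an error rather
#' than silently extrapolating.
#'
#' @param traj an `lc_trajectory` from [simulate_population()].
#' @param obs an [observation_set()] (only the strata columns are used);
#'   tables for the other sex are ignored via the `sex` column.
#' @return A list with one numeric vector per table: `incidence`, `deaths`,
#'   `other_deaths`, `population` (Poisson means, aligned with the table
#'   rows) and `prevalence` (binomial proportions).
#' @export
expected_observations <- function(traj, obs) {
  if (!inherits(traj, "lc_trajectory"))
    stop("`traj` must be an `lc_trajectory`", call. = FALSE)
  g <- traj$grid
  sex <- g$sex
  flow_of <- c(incidence = "new_cases", deaths = "cancer_deaths",
               other_deaths = "other_deaths")
  out <- list()
  for (nm in names(flow_of)) {
    tab <- obs[[nm]]
    tab <- tab[tab$sex == sex, , drop = FALSE]
    out[[nm]] <- .stratum_sums(traj$flows[flow_of[[nm]], , , drop = TRUE],
                               tab, g, first_year = g$t0,
                               last_year = g$t_max - 1L, what = nm)
  }
  pop_tot <- apply(traj$states, c(2, 3), sum)
  tab <- obs$population
  tab <- tab[tab$sex == sex, , drop = FALSE]
  out$population <- .stratum_sums(pop_tot, tab, g, g$t0, g$t_max, "population")
  tab <- obs$prevalence
  tab <- tab[tab$sex == sex, , drop = FALSE]
  num <- .stratum_sums(traj$states["S", , ], tab, g, g$t0, g$t_max,
                       "prevalence")
  den <- .stratum_sums(pop_tot, tab, g, g$t0, g$t_max, "prevalence")
  out$prevalence <- ifelse(den > 0, num / den, 0)
  out
}

# sum an (age x year) value matrix over closed-open age strata
.stratum_sums <- function(values, tab, g, first_year, last_year, what) {
  if (is.null(tab) || nrow(tab) == 0L) return(numeric(0))
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  if (any(tab$year < first_year | tab$year > last_year))
    stop(sprintf("`%s` strata refer to years outside %d-%d", what,
                 first_year, last_year), call. = FALSE)
  if (any(tab$age_lo < g$a0 | tab$age_lo > g$a_max | tab$age_hi <= g$a0))
    stop(sprintf("`%s` strata refer to ages outside the grid (%d-%d)", what,
                 g$a0, g$a_max), call. = FALSE)
  cs <- rbind(0, apply(values, 2, cumsum))
  t_idx <- tab$year - first_year + 1L
  lo_i <- pmax(tab$age_lo, g$a0) - g$a0 + 1L
  hi_i <- pmin(tab$age_hi - 1, g$a_max) - g$a0 + 1L
  cs[cbind(hi_i + 1L, t_idx)] - cs[cbind(lo_i, t_idx)]
}
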