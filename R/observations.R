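#' Observed data tables
#'
#' Bundles the six stratified tables the model is fitted to and projected
#' with: lung cancer incidence counts, lung cancer death counts,
#' current-smoker prevalence from surveys, population counts by single year
#' of age, deaths from all causes other than lung cancer, and the exogenous
#' projected population for the forecast horizon. Age intervals are
#' closed-open `[age_lo, age_hi)` (use `Inf` for an open top group); years
#' label Jan-1 cohorts.
#'
#' Count tables (`incidence`, `deaths`, `other_deaths`, `population`,
#' `projected_population`) have columns `sex`, `year`, `age_lo`, `age_hi`,
#' `count`. The `prevalence` table has `sex`, `year`, `age_lo`, `age_hi`,
#' `numerator`, `denominator` (current smokers over respondents).
#'
#' @param incidence,deaths,prevalence,population,other_deaths data frames
#'   as described above.
#' @param projected_population data frame, may be `NULL` when no forecast
#'   is planned.
#' @return An object of class `lc_observations`.
#' @export
observation_set <- function(incidence, deaths, prevalence, population,
                            other_deaths, projected_population = NULL) {
  obs <- structure(
    list(incidence = incidence, deaths = deaths, prevalence = prevalence,
         population = population, other_deaths = other_deaths,
         projected_population = projected_population),
    class = "lc_observations"
  )
  problems <- validate_observations(obs, error = FALSE)
  if (length(problems))
    stop(paste(c("invalid observation set:", paste0("  - ", problems)),
               collapse = "\n"), call. = FALSE)
  obs
}

.count_tables <- c("incidence", "deaths", "population", "other_deaths")
.obs_files <- c(incidence = "incidence.csv",
                deaths = "lung_cancer_deaths.csv",
                prevalence = "smoking_prevalence.csv",
                population = "population.csv",
                other_deaths = "other_cause_deaths.csv",
                projected_population = "projected_population.csv")

#' @export
print.lc_observations <- function(x, ...) {
  cat("<lc_observations>\n")
  for (nm in names(x)) {
    tab <- x[[nm]]
    if (is.null(tab) || !nrow(tab)) {
      cat(sprintf("  %-21s <absent>\n", nm)); next
    }
    cat(sprintf("  %-21s %5d rows, years %d-%d, sexes: %s\n", nm, nrow(tab),
                min(tab$year), max(tab$year),
                paste(sort(unique(tab$sex)), collapse = ", ")))
  }
  invisible(x)
}

#' Validate an observation set
#'
#' Checks schema, types, nonnegativity, prevalence numerators against
#' denominators, sex labels, age-interval sanity and year-coverage gaps.
#' All violations are collected and reported together.
#'
#' @param obs an `lc_observations` object (or plain list with the same
#'   element names).
#' @param error if `TRUE` (default), stop with a report listing every
#'   violation; if `FALSE`, return the violations as a character vector
#'   (empty when the set is valid).
#' @return Invisibly `obs` when valid; otherwise see `error`.
#' @export
validate_observations <- function(obs, error = TRUE) {
  problems <- character()
  note <- function(fmt, ...) problems <<- c(problems, sprintf(fmt, ...))

  for (nm in .count_tables) {
    tab <- obs[[nm]]
    if (is.null(tab)) { note("table `%s` is missing", nm); next }
    problems <- c(problems, .check_table(tab, nm, "count"))
  }
  if (!is.null(obs$projected_population))
    problems <- c(problems,
                  .check_table(obs$projected_population,
                               "projected_population", "count"))
  tab <- obs$prevalence
  if (is.null(tab)) {
    note("table `prevalence` is missing")
  } else {
    problems <- c(problems, .check_table(tab, "prevalence",
                                         c("numerator", "denominator")))
    if (all(c("numerator", "denominator") %in% names(tab))) {
      bad <- which(tab$numerator > tab$denominator)
      if (length(bad))
        note("prevalence numerator exceeds denominator in %d row(s) (first: row %d)",
             length(bad), bad[1L])
    }
  }
  # year-coverage gaps, per table and sex
  for (nm in c(.count_tables, "prevalence")) {
    tab <- obs[[nm]]
    if (is.null(tab) || !all(c("sex", "year") %in% names(tab))) next
    for (sx in unique(tab$sex)) {
      yrs <- sort(unique(tab$year[tab$sex == sx]))
      if (!length(yrs)) next
      gaps <- setdiff(seq(min(yrs), max(yrs)), yrs)
      if (length(gaps))
        note("table `%s` (%s) has year gaps: %s", nm, sx,
             paste(gaps, collapse = ", "))
    }
  }
  if (error) {
    if (length(problems))
      stop(paste(c("invalid observation set:", paste0("  - ", problems)),
                 collapse = "\n"), call. = FALSE)
    return(invisible(obs))
  }
  problems
}

.check_table <- function(tab, nm, value_cols) {
  problems <- character()
  need <- c("sex", "year", "age_lo", "age_hi", value_cols)
  if (!is.data.frame(tab))
    return(sprintf("table `%s` is not a data frame", nm))
  miss <- setdiff(need, names(tab))
  if (length(miss))
    return(sprintf("table `%s` lacks column(s): %s", nm,
                   paste(miss, collapse = ", ")))
  if (!all(tab$sex %in% c("male", "female")))
    problems <- c(problems,
                  sprintf("table `%s` has sex labels outside {male, female}", nm))
  for (col in c("year", "age_lo", "age_hi", value_cols)) {
    v <- tab[[col]]
    if (!is.numeric(v) || anyNA(v)) {
      problems <- c(problems,
                    sprintf("table `%s` column `%s` must be numeric without NA",
                            nm, col))
      next
    }
    if (col %in% value_cols && any(v < 0))
      problems <- c(problems,
                    sprintf("table `%s` column `%s` has negative values", nm, col))
  }
  if (is.numeric(tab$age_lo) && is.numeric(tab$age_hi) &&
      !anyNA(tab$age_lo) && !anyNA(tab$age_hi) &&
      any(tab$age_hi <= tab$age_lo))
    problems <- c(problems,
                  sprintf("table `%s` has rows with age_hi <= age_lo", nm))
  problems
}

#' Read and write observation sets as CSV
#'
#' An observation set is stored as one CSV per table in a directory:
#' `incidence.csv`, `lung_cancer_deaths.csv`, `smoking_prevalence.csv`,
#' `population.csv`, `other_cause_deaths.csv` and (optionally)
#' `projected_population.csv`, with the column schemas described in
#' [observation_set()]. `Inf` upper age bounds are written as the string
#' `Inf` and read back.
#'
#' @param obs an `lc_observations` object.
#' @param dir directory to write to / read from (created if needed).
#' @return `write_observations()` returns the directory invisibly;
#'   `read_observations()` returns a validated `lc_observations`.
#' @export
write_observations <- function(obs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(.obs_files)) {
    if (is.null(obs[[nm]])) next
    write.csv(obs[[nm]], file.path(dir, .obs_files[[nm]]), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_observations
#' @export
read_observations <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("no such directory: %s", dir), call. = FALSE)
  tabs <- lapply(names(.obs_files), function(nm) {
    path <- file.path(dir, .obs_files[[nm]])
    if (!file.exists(path)) {
      if (nm == "projected_population") return(NULL)
      stop(sprintf("missing required file: %s", path), call. = FALSE)
    }
    tab <- read.csv(path)
    if ("age_hi" %in% names(tab)) tab$age_hi <- as.numeric(tab$age_hi)
    tab
  })
  names(tabs) <- names(.obs_files)
  observation_set(tabs$incidence, tabs$deaths, tabs$prevalence,
                  tabs$population, tabs$other_deaths,
                  tabs$projected_population)
}

# restrict an observation set to one sex (drops empty tables' rows)
.obs_for_sex <- function(obs, sex) {
  out <- lapply(obs, function(tab) {
    if (is.null(tab)) return(NULL)
    tab[tab$sex == sex, , drop = FALSE]
  })
  class(out) <- "lc_observations"
  out
}
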