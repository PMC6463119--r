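#' Transition-rate surfaces on the (year, age) grid
#'
#' The model is driven by five nonnegative rate surfaces, each a per
#' person-year hazard defined on every (calendar year, age) cell:
#' `sigma` smoking uptake (M to S), `delta` cessation (S to E), `lambda`
#' never-smoker lung cancer incidence (multiplied by `kS`/`kE` for
#' smokers/ex-smokers), `mu` non-lung-cancer mortality and `nu` excess
#' lung-cancer mortality acting on diagnosed patients.
#'
#' Each surface may be given as a single number (constant), a
#' `n_years x n_ages` matrix (rows are years `t0:t_max`, columns ages
#' `a0:a_max`), or a function `f(year, age)` that is evaluated on the grid
#' via [outer()].
#'
#' @param grid an [lc_grid()].
#' @param sigma,delta,lambda,mu,nu surface specifications (see Details).
#' @return An object of class `lc_rates`: a list of five matrices with
#'   year/age dimnames, carrying the grid as an attribute.
#' @examples
#' g <- lc_grid(2000, 2010, a0 = 0, a_max = 20)
#' rs <- rate_surfaces(g, sigma = 0.05, delta = 0.02, lambda = 1e-4,
#'                     mu = function(t, a) 1e-4 * exp(0.08 * a), nu = 0.25)
#' @export
rate_surfaces <- function(grid, sigma, delta, lambda, mu, nu) {
  grid <- .check_grid(grid)
  spec <- list(sigma = sigma, delta = delta, lambda = lambda, mu = mu, nu = nu)
  years <- grid_years(grid)
  ages <- grid_ages(grid)
  out <- lapply(.rate_symbols, function(sym) {
    m <- .as_surface_matrix(spec[[sym]], years, ages, sym)
    .check_surface_values(m, sym)
    m
  })
  names(out) <- .rate_symbols
  structure(out, grid = grid, class = "lc_rates")
}

.as_surface_matrix <- function(x, years, ages, sym) {
  if (is.function(x)) {
    m <- outer(years, ages, x)
  } else if (is.matrix(x)) {
    if (nrow(x) != length(years) || ncol(x) != length(ages))
      stop(sprintf("surface `%s` must be %d x %d (years x ages)",
                   sym, length(years), length(ages)), call. = FALSE)
    m <- x
  } else if (is.numeric(x) && length(x) == 1L) {
    m <- matrix(x, length(years), length(ages))
  } else {
    stop(sprintf("surface `%s` must be a scalar, matrix or function(year, age)",
                 sym), call. = FALSE)
  }
  dimnames(m) <- list(year = years, age = ages)
  m
}

.check_surface_values <- function(m, sym) {
  if (any(!is.finite(m)) || any(m < 0))
    stop(sprintf("rate surface `%s` contains negative or non-finite values",
                 sym), call. = FALSE)
  invisible(m)
}

#' @export
print.lc_rates <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<lc_rates> %s, years %d-%d, ages %d-%d\n",
              g$sex, g$t0, g$t_max, g$a0, g$a_max))
  for (sym in .rate_symbols)
    cat(sprintf("  %-6s range [%.3g, %.3g]\n", sym, min(x[[sym]]), max(x[[sym]])))
  invisible(x)
}

# per-age rate vectors for one calendar year; errors rather than extrapolates
.rates_at_year <- function(rates, year) {
  g <- attr(rates, "grid")
  if (year < g$t0 || year > g$t_max)
    stop(sprintf("no rates defined for year %d (surfaces cover %d-%d)",
                 year, g$t0, g$t_max), call. = FALSE)
  i <- year - g$t0 + 1L
  lapply(rates, function(m) m[i, ])
}

.check_rates <- function(rates) {
  if (!inherits(rates, "lc_rates"))
    stop("expected an `lc_rates` object (see `rate_surfaces()`)", call. = FALSE)
  rates
}

#' Extend rate surfaces over a forecast horizon
#'
#' Forecast-horizon rates are carried forward: every cell in a year after
#' `last_fitted_year` takes the value of the same age cell at
#' `last_fitted_year`, preserving the most recently fitted age profile
#' verbatim. The operation is idempotent, and a `horizon_end` at or before
#' `last_fitted_year` is a no-op.
#'
#' @param rates an `lc_rates` object complete through `last_fitted_year`.
#' @param last_fitted_year final year whose rates are data-supported.
#' @param horizon_end last calendar year the returned surfaces must cover.
#' @return An `lc_rates` object covering `t0` to
#'   `max(horizon_end, last_fitted_year)`; any values previously present
#'   after `last_fitted_year` are replaced by the carry-forward rule.
#' @export
extend_forecast <- function(rates, last_fitted_year, horizon_end) {
  rates <- .check_rates(rates)
  g <- attr(rates, "grid")
  if (last_fitted_year < g$t0 || last_fitted_year > g$t_max)
    stop("`last_fitted_year` is outside the fitted surfaces", call. = FALSE)
  t_end <- max(as.integer(horizon_end), as.integer(last_fitted_year))
  new_years <- g$t0:t_end
  keep <- g$t0:last_fitted_year
  ref <- as.integer(last_fitted_year) - g$t0 + 1L
  out <- lapply(rates, function(m) {
    res <- matrix(NA_real_, length(new_years), ncol(m))
    res[seq_along(keep), ] <- m[seq_along(keep), , drop = FALSE]
    if (t_end > last_fitted_year)
      res[(length(keep) + 1L):length(new_years), ] <-
        matrix(m[ref, ], t_end - last_fitted_year, ncol(m), byrow = TRUE)
    dimnames(res) <- list(year = new_years, age = colnames(m))
    res
  })
  new_grid <- lc_grid(g$t0, t_end, g$a0, g$a_max, g$sex)
  structure(out, grid = new_grid, class = "lc_rates")
}
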