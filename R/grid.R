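#' Simulation grid
#'
#' Defines the (calendar year, age) lattice on which the compartmental model
#' is solved. The time step and age step are both one year, so birth cohorts
#' travel along characteristics: the cohort occupying age `a` in year `t`
#' occupies age `a + 1` in year `t + 1`. Ages at or above `a_max` are pooled
#' in a closed top bin that keeps experiencing the oldest cell's rates.
#'
#' @param t0 first calendar year (integer).
#' @param t_max last calendar year (integer, `> t0`).
#' @param a0 youngest modelled age in years (default 0).
#' @param a_max oldest modelled age; the top bin is closed (default 100).
#' @param sex `"male"` or `"female"`; a grid describes one sex.
#' @return An object of class `lc_grid`.
#' @examples
#' g <- lc_grid(1970, 2014, sex = "male")
#' grid_years(g)[1:3]
#' @export
lc_grid <- function(t0, t_max, a0 = 0, a_max = 100,
                    sex = c("male", "female")) {
  sex <- match.arg(sex)
  t0 <- as.integer(t0); t_max <- as.integer(t_max)
  a0 <- as.integer(a0); a_max <- as.integer(a_max)
  if (!(t0 < t_max)) stop("`t0` must be strictly before `t_max`", call. = FALSE)
  if (!(a0 < a_max)) stop("`a0` must be strictly below `a_max`", call. = FALSE)
  if (a0 < 0) stop("`a0` must be nonnegative", call. = FALSE)
  structure(
    list(t0 = t0, t_max = t_max, a0 = a0, a_max = a_max, sex = sex),
    class = "lc_grid"
  )
}

#' @rdname lc_grid
#' @param grid an `lc_grid`.
#' @export
grid_years <- function(grid) grid$t0:grid$t_max

#' @rdname lc_grid
#' @export
grid_ages <- function(grid) grid$a0:grid$a_max

#' @export
print.lc_grid <- function(x, ...) {
  cat(sprintf("<lc_grid> %s, years %d-%d, ages %d-%d (closed top bin)\n",
              x$sex, x$t0, x$t_max, x$a0, x$a_max))
  invisible(x)
}

.is_grid <- function(x) inherits(x, "lc_grid")

.check_grid <- function(grid) {
  if (!.is_grid(grid)) stop("expected an `lc_grid` object", call. = FALSE)
  grid
}
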