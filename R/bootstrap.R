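#' Parametric bootstrap from the inverse Hessian
#'
#' Draws replicate parameter vectors from a multivariate normal
#' distribution centred at the maximum-likelihood estimate with covariance
#' equal to the inverse Hessian of the negative log-likelihood (drawn on
#' the log-rate scale, where the likelihood was maximized), evaluates a
#' user-supplied output functional for each draw, and summarizes the
#' replicate outputs by elementwise percentiles. With the default 95%
#' level the bands are the 2.5th and 97.5th percentiles of the simulated
#' distribution.
#'
#' @param fit an `lc_fit` with a computed covariance.
#' @param output_fn function mapping a parameter vector to a numeric
#'   vector of outputs; defaults to the identity (the parameters
#'   themselves).
#' @param n_reps number of bootstrap replicates (the reference analysis
#'   uses 1000).
#' @param seed integer seed; all randomness of the bootstrap flows from it.
#' @param level coverage of the percentile band (default 0.95).
#' @return An object of class `lc_bootstrap`: `draws` (`n_reps x p`),
#'   `outputs` (`n_reps x m`), `bands` (rows `lower`, `median`, `upper`),
#'   `n_reps`, `seed`, `level`.
#' @export
parametric_bootstrap <- function(fit, output_fn = NULL, n_reps = 1000,
                                 seed, level = 0.95) {
  if (!inherits(fit, "lc_fit")) stop("`fit` must be an `lc_fit`", call. = FALSE)
  if (is.null(fit$covariance))
    stop("`fit` has no covariance; rerun `fit_mle()` with `hessian = TRUE`",
         call. = FALSE)
  if (missing(seed) || is.null(seed))
    stop("a `seed` is required for reproducibility", call. = FALSE)
  if (n_reps < 1) stop("`n_reps` must be at least 1", call. = FALSE)
  output_fn <- output_fn %||% function(theta) theta
  draws <- .draw_parameters(fit, n_reps, seed)
  first <- output_fn(draws[1L, ])
  outputs <- matrix(NA_real_, n_reps, length(first),
                    dimnames = list(NULL, names(first)))
  outputs[1L, ] <- first
  if (n_reps > 1L)
    for (i in 2:n_reps) outputs[i, ] <- output_fn(draws[i, ])
  structure(list(draws = draws, outputs = outputs,
                 bands = .percentile_bands(outputs, level),
                 n_reps = n_reps, seed = seed, level = level),
            class = "lc_bootstrap")
}

.draw_parameters <- function(fit, n_reps, seed) {
  set.seed(as.integer(seed))
  draws <- try(MASS::mvrnorm(n_reps, mu = fit$theta_hat,
                             Sigma = fit$covariance), silent = TRUE)
  if (inherits(draws, "try-error"))
    stop("covariance is not positive semidefinite even after repair; ",
         "coarsen the block structure and refit", call. = FALSE)
  if (n_reps == 1L) draws <- matrix(draws, nrow = 1L)
  colnames(draws) <- names(fit$theta_hat)
  draws
}

.percentile_bands <- function(outputs, level) {
  alpha <- (1 - level) / 2
  bands <- apply(outputs, 2, quantile, probs = c(alpha, 0.5, 1 - alpha),
                 names = FALSE)
  if (is.null(dim(bands))) bands <- matrix(bands, nrow = 3L)
  rownames(bands) <- c("lower", "median", "upper")
  colnames(bands) <- colnames(outputs)
  bands
}

#' @export
print.lc_bootstrap <- function(x, ...) {
  cat(sprintf("<lc_bootstrap> %d replicates, %d outputs, %.0f%% bands (seed %s)\n",
              x$n_reps, ncol(x$outputs), 100 * x$level, format(x$seed)))
  invisible(x)
}
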