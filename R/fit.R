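#' Maximum-likelihood fit of the rate surfaces
#'
#' Maximizes the composite log-likelihood over the log-rate parameter
#' vector with a bounded quasi-Newton optimizer (L-BFGS-B with
#' finite-difference gradients; box bounds on the log rates keep the
#' search away from the degenerate zero-rate boundary, where the log-scale
#' gradient vanishes), then evaluates the Hessian of the negative
#' log-likelihood at the optimum by finite differences; its inverse is the
#' parameter covariance used by the parametric bootstrap. The covariance is
#' symmetrized and, if numerically indefinite, repaired by clipping
#' negative eigenvalues at a small floor (flagged in the result).
#'
#' Before optimizing, every estimated block is checked for identifiability:
#' a block must overlap at least one stratum of the dataset that informs
#' its symbol (`lambda`: incidence, `nu`: lung cancer deaths, `mu`:
#' other-cause deaths, `sigma`/`delta`: smoking prevalence at the block's
#' ages or older, since uptake is observed later along the cohort's
#' characteristic). Unidentifiable blocks raise an error listing them.
#'
#' @param obs an [observation_set()]; only rows matching the grid's sex are
#'   used.
#' @param fixed an [hazard_ratios()] object (not estimated).
#' @param blocks an [block_structure()] on the fitting grid.
#' @param inputs an [model_inputs()] object.
#' @param init optional numeric start vector (log rates); defaults to
#'   crude data-derived rates via [initial_theta()].
#' @param control list passed to [stats::optim()] (`maxit`, `factr`,
#'   `pgtol`, `ndeps`, ...), plus `lower` / `upper` box bounds on the log
#'   rates (defaults -16 and 5) and `hess_ndeps`, the finite-difference
#'   step of the Hessian evaluation (default 5e-3).
#' @param hessian compute the Hessian/covariance (default `TRUE`).
#' @return An object of class `lc_fit`: `theta_hat`, `loglik`,
#'   `covariance`, `hessian`, `convergence` (0 = converged),
#'   `psd_repaired`, plus the `blocks`, `fixed`, `inputs` and `obs` the
#'   fit was made with.
#' @export
fit_mle <- function(obs, fixed, blocks, inputs, init = NULL,
                    control = list(), hessian = TRUE) {
  blocks <- .check_blocks(blocks)
  fixed <- .check_hr(fixed)
  g <- blocks$grid
  if (!identical(unclass(g), unclass(inputs$grid)))
    stop("`blocks` and `inputs` are on different grids", call. = FALSE)
  .check_identifiable(obs, blocks)
  if (is.null(init)) init <- initial_theta(obs, blocks)
  if (length(init) != blocks$n_params)
    stop("`init` length does not match the block structure", call. = FALSE)

  # strata indices are precomputed once; structural problems (bad strata,
  # grid mismatches) surface here and in the first, unguarded evaluation
  pre <- .precompute_strata(obs, g)
  sim_ll <- function(theta) {
    traj <- simulate_population(expand_rates(theta, blocks), fixed,
                                inputs$initial_state, inputs$inflow)
    .loglik_indexed(traj, pre)
  }
  sim_ll(init)
  # numerical failures of the matrix exponential (possible only at extreme
  # rates) are mapped to a large penalty instead of aborting a line search
  negll <- function(theta) {
    v <- tryCatch(sim_ll(theta), error = function(e) -Inf)
    if (!is.finite(v)) return(1e12)
    -v
  }
  # bounded quasi-Newton on the log-rate scale: the lower bound stops
  # rates from collapsing toward zero into the flat log-scale boundary
  # (where the gradient d ll / d log(rate) vanishes and the optimizer
  # would stall); the upper bound caps hazards at e^5 per person-year
  lower <- control$lower %||% -16
  upper <- control$upper %||% 5
  ctrl <- utils::modifyList(list(maxit = 500L, factr = 1e7, lmm = 20),
                            control)
  ctrl$hess_ndeps <- NULL; ctrl$lower <- NULL; ctrl$upper <- NULL
  ctrl$precondition <- NULL; ctrl$max_var <- NULL
  init <- pmin(pmax(init, lower + 1e-8), upper - 1e-8)
  # diagonal preconditioning: curvatures in this model span several orders
  # of magnitude (population counts pin mortality far harder than sparse
  # cancer counts pin hazards), which cripples an unscaled quasi-Newton
  # search on larger parameter vectors
  precond <- control$precondition %||% (blocks$n_params >= 10L)
  if (isTRUE(precond) && is.null(ctrl$parscale)) {
    h <- 0.05
    f0 <- negll(init)
    if (f0 < 1e11) {
      d2 <- vapply(seq_along(init), function(k) {
        e <- (seq_along(init) == k) * h
        (negll(init + e) - 2 * f0 + negll(init - e)) / h^2
      }, numeric(1))
      d2 <- pmax(d2, 1)
      ctrl$parscale <- sqrt(stats::median(d2) / d2)
    }
  }
  opt <- optim(init, negll, method = "L-BFGS-B", lower = lower,
               upper = upper, control = ctrl)
  theta_hat <- setNames(opt$par, blocks$param_names)

  H <- cov <- NULL
  psd_repaired <- FALSE
  if (hessian) {
    # a larger step than the optimizer's keeps the second differences of a
    # log-likelihood of magnitude ~1e5 above double-precision roundoff
    h_step <- control$hess_ndeps %||% 5e-3
    H <- optimHess(theta_hat, negll,
                   control = list(ndeps = rep(h_step, length(theta_hat))))
    H <- (H + t(H)) / 2
    cv <- try(solve(H), silent = TRUE)
    if (inherits(cv, "try-error")) {
      ev <- eigen(H, symmetric = TRUE)
      floor_ev <- max(abs(ev$values)) * 1e-10
      vals <- pmax(ev$values, floor_ev)
      cv <- ev$vectors %*% diag(1 / vals, length(vals)) %*% t(ev$vectors)
      psd_repaired <- TRUE
    }
    cv <- (cv + t(cv)) / 2
    # repair: negative eigenvalues (indefinite finite-difference Hessian)
    # are floored, and near-singular directions — typically parameters
    # resting on a box bound — are capped so that no direction's standard
    # deviation exceeds ~2 on the log scale; otherwise bootstrap draws
    # from the repaired covariance explode to meaningless rates
    var_cap <- control$max_var %||% 4
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 0 || max(ev) > var_cap) {
      e <- eigen(cv, symmetric = TRUE)
      floor_ev <- max(abs(e$values)) * 1e-12
      vals <- pmin(pmax(e$values, floor_ev), var_cap)
      cv <- e$vectors %*% diag(vals, length(vals)) %*% t(e$vectors)
      cv <- (cv + t(cv)) / 2
      psd_repaired <- TRUE
    }
    if (psd_repaired)
      warning("covariance repaired to positive semidefinite; consider coarser blocks",
              call. = FALSE)
    dimnames(cv) <- dimnames(H) <- list(blocks$param_names, blocks$param_names)
    cov <- cv
  }
  structure(list(theta_hat = theta_hat, loglik = -opt$value,
                 covariance = cov, hessian = H,
                 convergence = opt$convergence, counts = opt$counts,
                 message = opt$message, psd_repaired = psd_repaired,
                 blocks = blocks, fixed = fixed, inputs = inputs, obs = obs),
            class = "lc_fit")
}

#' @export
print.lc_fit <- function(x, ...) {
  cat(sprintf("<lc_fit> %s, %d parameters, log-likelihood %.4f\n",
              x$blocks$grid$sex, length(x$theta_hat), x$loglik))
  cat(sprintf("  convergence code %d (%s); covariance %s\n", x$convergence,
              if (x$convergence == 0) "converged" else "NOT converged",
              if (is.null(x$covariance)) "not computed"
              else if (x$psd_repaired) "PSD-repaired" else "ok"))
  invisible(x)
}

#' Crude data-derived starting values
#'
#' Builds a starting log-rate vector from the observed tables: per-block
#' crude rates for `lambda` (incidence over person-years), `mu`
#' (other-cause deaths over person-years) and `nu` (lung cancer deaths
#' over an assumed patient pool), and prevalence-guided constants for
#' `sigma` and `delta`. Values are clamped to a reasonable hazard range;
#' blocks without overlapping data fall back to table-wide crude rates.
#'
#' @inheritParams fit_mle
#' @return Named numeric vector of log rates, one per estimated block.
#' @export
initial_theta <- function(obs, blocks) {
  blocks <- .check_blocks(blocks)
  g <- blocks$grid
  obs <- .obs_for_sex(obs, g$sex)
  pop <- obs$population
  py <- function(t_lo, t_hi, a_lo, a_hi) {
    sel <- pop$year >= t_lo & pop$year < t_hi &
      pop$age_lo >= a_lo & pop$age_lo < a_hi
    sum(pop$count[sel])
  }
  crude <- function(tab, t_lo, t_hi, a_lo, a_hi, fallback) {
    sel <- tab$year >= t_lo & tab$year < t_hi &
      pmin(tab$age_hi, g$a_max + 1) > a_lo & tab$age_lo < a_hi
    events <- sum(tab$count[sel])
    denom <- py(t_lo, t_hi, a_lo, a_hi)
    if (events > 0 && denom > 0) events / denom else fallback
  }
  tot_py <- max(sum(pop$count), 1)
  lam0 <- max(sum(obs$incidence$count) / tot_py, 1e-8)
  mu0 <- max(sum(obs$other_deaths$count) / tot_py, 1e-8)
  prev_bar <- if (nrow(obs$prevalence))
    max(sum(obs$prevalence$numerator) / sum(obs$prevalence$denominator), 1e-3)
  else 0.2
  # crude uptake so cumulative initiation over ~15 adult years matches
  sig0 <- min(max(-log(1 - min(prev_bar * 1.3, 0.95)) / 15, 1e-4), 0.3)
  defaults <- c(sigma = sig0, delta = 0.03, lambda = lam0, mu = mu0, nu = 0.2)
  src <- list(lambda = obs$incidence, mu = obs$other_deaths,
              nu = obs$deaths)
  theta <- numeric(blocks$n_params)
  b <- blocks$blocks
  for (i in seq_len(nrow(b))) {
    sym <- b$symbol[i]
    val <- if (sym %in% names(src)) {
      r <- crude(src[[sym]], b$t_lo[i], b$t_hi[i], b$a_lo[i], b$a_hi[i],
                 defaults[[sym]])
      if (sym == "nu") defaults[["nu"]] else r
    } else defaults[[sym]]
    theta[i] <- log(min(max(val, 1e-8), 2))
  }
  setNames(theta, blocks$param_names)
}

# every estimated block must touch at least one informative stratum
.check_identifiable <- function(obs, blocks) {
  g <- blocks$grid
  obs <- .obs_for_sex(obs, g$sex)
  informant <- list(lambda = obs$incidence, nu = obs$deaths,
                    mu = obs$other_deaths,
                    sigma = obs$prevalence, delta = obs$prevalence)
  b <- blocks$blocks
  bad <- character()
  for (i in seq_len(nrow(b))) {
    sym <- b$symbol[i]
    tab <- informant[[sym]]
    if (is.null(tab) || !nrow(tab)) { bad <- c(bad, rownames(b)[i]); next }
    hi <- pmin(tab$age_hi, g$a_max + 1)
    ok <- if (sym %in% c("sigma", "delta")) {
      # uptake/cessation at (t, a) surfaces in prevalence surveys of the
      # same or older ages, in the same or later years
      any(hi > b$a_lo[i] & tab$year >= b$t_lo[i])
    } else {
      any(hi > b$a_lo[i] & tab$age_lo < b$a_hi[i] &
            tab$year >= b$t_lo[i] & tab$year < b$t_hi[i])
    }
    if (!ok) bad <- c(bad, rownames(b)[i])
  }
  if (length(bad))
    stop(paste(c("unidentifiable blocks (no informative strata):",
                 paste0("  - ", bad)), collapse = "\n"), call. = FALSE)
  invisible(TRUE)
}
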