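#' Piecewise-constant parameterization of the rate surfaces
#'
#' The estimated parameter vector theta holds one log-rate per
#' (rate symbol, time block, age block). Blocks are defined by closed-open
#' edge sequences per symbol; cells at ages outside a symbol's age-edge
#' coverage are structurally zero (not estimated), which is how smoking
#' uptake and cessation are switched off in childhood. Defaults follow the
#' strata of the observed data: 5-year age blocks for `lambda`, `mu`, `nu`,
#' 10-year age blocks from age 20 for `sigma` and `delta`, and one time
#' block per calendar year (configurable to multi-year blocks).
#'
#' @param grid the fitting [lc_grid()]; blocks cover its years and ages.
#' @param age_edges named list of ascending age-edge vectors per symbol
#'   (closed-open blocks `[e_i, e_{i+1})`; `Inf` is capped at `a_max + 1`).
#'   Missing symbols get defaults.
#' @param time_edges named list of year-edge vectors per symbol, or a single
#'   unnamed vector shared by all symbols; default annual blocks.
#' @param time_block_width convenience: width in years of regular time
#'   blocks (used when `time_edges` is `NULL`).
#' @return An object of class `lc_blocks` with one parameter index matrix
#'   per symbol.
#' @export
block_structure <- function(grid, age_edges = list(), time_edges = NULL,
                            time_block_width = 1) {
  grid <- .check_grid(grid)
  ages <- grid_ages(grid)
  years <- grid_years(grid)
  a_cap <- grid$a_max + 1L
  t_cap <- grid$t_max + 1L

  smoke_edges <- if (grid$a_max > 20L)
    c(seq(20L, min(60L, grid$a_max), by = 10L), a_cap)
  else c(grid$a0, a_cap)
  def_age <- list(
    sigma = smoke_edges,
    delta = smoke_edges,
    lambda = c(seq(grid$a0, grid$a_max, by = 5L), a_cap),
    mu = c(seq(grid$a0, grid$a_max, by = 5L), a_cap),
    nu = c(seq(grid$a0, grid$a_max, by = 5L), a_cap)
  )
  def_time <- c(seq(grid$t0, grid$t_max, by = as.integer(time_block_width)),
                t_cap)
  if (!is.null(time_edges) && !is.list(time_edges))
    time_edges <- setNames(rep(list(time_edges), 5L), .rate_symbols)
  time_edges <- time_edges %||% list()

  index <- list(); param_names <- character(); table <- list()
  next_id <- 0L
  for (sym in .rate_symbols) {
    ae_raw <- age_edges[[sym]] %||% def_age[[sym]]
    if (length(ae_raw) == 0L) {
      # symbol switched off: structurally zero surface, nothing estimated
      index[[sym]] <- matrix(0L, length(years), length(ages),
                             dimnames = list(year = years, age = ages))
      next
    }
    ae <- .clean_edges(ae_raw, a_cap, sprintf("age edges for `%s`", sym))
    te <- .clean_edges(time_edges[[sym]] %||% def_time, t_cap,
                       sprintf("time edges for `%s`", sym))
    n_ab <- length(ae) - 1L
    n_tb <- length(te) - 1L
    ab <- findInterval(ages, ae)          # 0 or n_ab+1 => structural zero
    tb <- findInterval(years, te)
    idx <- matrix(0L, length(years), length(ages),
                  dimnames = list(year = years, age = ages))
    local_id <- matrix(seq_len(n_tb * n_ab), n_tb, n_ab)
    inside_a <- ab >= 1L & ab <= n_ab
    inside_t <- tb >= 1L & tb <= n_tb
    if (!all(inside_t))
      stop(sprintf("time edges for `%s` must cover all grid years", sym),
           call. = FALSE)
    idx[, inside_a] <- local_id[cbind(rep(tb, sum(inside_a)),
                                      rep(ab[inside_a], each = length(tb)))]
    idx[idx > 0L] <- idx[idx > 0L] + next_id
    index[[sym]] <- idx
    nm <- as.vector(outer(seq_len(n_tb), seq_len(n_ab), function(i, j)
      sprintf("%s[%d,%d]", sym, te[i], ae[j])))
    param_names <- c(param_names, nm)
    table[[sym]] <- data.frame(
      symbol = sym,
      t_lo = rep(te[seq_len(n_tb)], n_ab),
      t_hi = rep(te[-1L], n_ab),
      a_lo = rep(ae[seq_len(n_ab)], each = n_tb),
      a_hi = rep(ae[-1L], each = n_tb)
    )
    next_id <- next_id + n_tb * n_ab
  }
  blocks <- do.call(rbind, table)
  rownames(blocks) <- param_names
  structure(list(grid = grid, index = index, blocks = blocks,
                 n_params = next_id, param_names = param_names),
            class = "lc_blocks")
}

.clean_edges <- function(edges, cap, what) {
  edges <- as.numeric(edges)
  edges[is.infinite(edges)] <- cap
  edges <- pmin(edges, cap)
  edges <- unique(as.integer(edges))
  if (length(edges) < 2L || any(diff(edges) <= 0))
    stop(sprintf("%s must be at least two strictly increasing values", what),
         call. = FALSE)
  edges
}

#' @export
print.lc_blocks <- function(x, ...) {
  per <- table(factor(x$blocks$symbol, levels = .rate_symbols))
  cat(sprintf("<lc_blocks> %d parameters (%s)\n", x$n_params,
              paste(sprintf("%s: %d", .rate_symbols, per), collapse = ", ")))
  invisible(x)
}

.check_blocks <- function(blocks) {
  if (!inherits(blocks, "lc_blocks"))
    stop("expected an `lc_blocks` object (see `block_structure()`)",
         call. = FALSE)
  blocks
}

#' Map between the parameter vector and rate surfaces
#'
#' `expand_rates()` turns a log-rate parameter vector into the five
#' piecewise-constant surfaces; `collapse_rates()` inverts it for surfaces
#' that are constant on blocks. The pair is a bijection on the block
#' structure: `collapse_rates(expand_rates(theta)) == theta` bit-exactly.
#'
#' @param theta numeric vector of log rates, length `blocks$n_params`.
#' @param blocks an [block_structure()].
#' @return `expand_rates()`: an `lc_rates` object; `collapse_rates()`: a
#'   named numeric vector of log rates.
#' @export
expand_rates <- function(theta, blocks) {
  blocks <- .check_blocks(blocks)
  if (length(theta) != blocks$n_params)
    stop(sprintf("`theta` has length %d but the block structure has %d parameters",
                 length(theta), blocks$n_params), call. = FALSE)
  if (any(!is.finite(theta)))
    stop("`theta` must be finite (log rates)", call. = FALSE)
  vals <- exp(theta)
  out <- lapply(.rate_symbols, function(sym) {
    idx <- blocks$index[[sym]]
    m <- matrix(0, nrow(idx), ncol(idx), dimnames = dimnames(idx))
    nz <- idx > 0L
    m[nz] <- vals[idx[nz]]
    m
  })
  names(out) <- .rate_symbols
  structure(out, grid = blocks$grid, class = "lc_rates")
}

#' @rdname expand_rates
#' @param rates an `lc_rates` object constant within each block.
#' @export
collapse_rates <- function(rates, blocks) {
  rates <- .check_rates(rates)
  blocks <- .check_blocks(blocks)
  theta <- numeric(blocks$n_params)
  for (sym in .rate_symbols) {
    idx <- blocks$index[[sym]]
    m <- rates[[sym]]
    if (!all(dim(m) == dim(idx)))
      stop("surfaces and block structure are on different grids", call. = FALSE)
    nz <- which(idx > 0L)
    first <- nz[!duplicated(idx[nz])]
    if (any(m[first] <= 0))
      stop(sprintf("surface `%s` has nonpositive values on estimated blocks; cannot take logs",
                   sym), call. = FALSE)
    theta[idx[first]] <- log(m[first])
  }
  setNames(theta, blocks$param_names)
}
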