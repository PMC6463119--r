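# Independent oracles used to cross-check the matrix-exponential cohort
# step. Both are written directly from the model equations, without touching
# the package's generator code.

# Right-hand side of the augmented within-cell ODE:
# y = (M, S, E, L, other_deaths, cancer_deaths, new_cases)
.oracle_rhs <- function(y, r, hr) {
  M <- y[1]; S <- y[2]; E <- y[3]; L <- y[4]
  onset <- r$lambda * (M + hr$kS * S + hr$kE * E)
  c(-(r$mu + r$sigma + r$lambda) * M,
    r$sigma * M - ((1 + hr$qS) * r$mu + r$delta + hr$kS * r$lambda) * S,
    r$delta * S - ((1 + hr$qE) * r$mu + hr$kE * r$lambda) * E,
    onset - (r$mu + r$nu) * L,
    r$mu * (M + L) + (1 + hr$qS) * r$mu * S + (1 + hr$qE) * r$mu * E,
    r$nu * L,
    onset)
}

# classic fixed-step RK4 on the augmented system over one unit of time
rk4_cell_oracle <- function(state, rates, hr, dt_total = 1, n_steps = 1e4) {
  r <- as.list(rates)
  y <- c(state, 0, 0, 0)
  h <- dt_total / n_steps
  for (i in seq_len(n_steps)) {
    k1 <- .oracle_rhs(y, r, hr)
    k2 <- .oracle_rhs(y + h / 2 * k1, r, hr)
    k3 <- .oracle_rhs(y + h / 2 * k2, r, hr)
    k4 <- .oracle_rhs(y + h * k3, r, hr)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  list(state = y[1:4],
       flows = c(new_cases = y[7], cancer_deaths = y[6], other_deaths = y[5]))
}

# Event-driven stochastic microsimulation of independent individuals.
# Within each (year, age) cell the rates are constant, so each agent's next
# event time is exponential with the current state's total exit rate, and
# competing events are chosen proportionally to their rates. Agent states:
# 1 M, 2 S, 3 E, 4 L, 5 dead (other causes), 6 dead (lung cancer).

# per-state competing-event rates and resulting states
.microsim_events <- function(r, hr) {
  list(list(rates = c(r$mu, r$sigma, r$lambda), to = c(5L, 2L, 4L)),
       list(rates = c((1 + hr$qS) * r$mu, r$delta, hr$kS * r$lambda),
            to = c(5L, 3L, 4L)),
       list(rates = c((1 + hr$qE) * r$mu, hr$kE * r$lambda), to = c(5L, 4L)),
       list(rates = c(r$mu, r$nu), to = c(5L, 6L)))
}

# advance all agents of one cell through one year; r holds scalar rates
microsim_year <- function(states, r, hr) {
  ev <- .microsim_events(r, hr)
  exit_rate <- vapply(ev, function(e) sum(e$rates), numeric(1))
  new_cases <- 0L
  t_rem <- rep(1, length(states))
  active <- which(states <= 4L)
  while (length(active)) {
    s <- states[active]
    rate <- exit_rate[s]
    tau <- rep(Inf, length(active))
    pos <- rate > 0
    tau[pos] <- stats::rexp(sum(pos), rate[pos])
    hit <- tau < t_rem[active]
    idx <- active[hit]
    if (length(idx)) {
      s_hit <- states[idx]
      for (st in 1:4) {
        sel <- idx[s_hit == st]
        if (!length(sel)) next
        e <- ev[[st]]
        u <- stats::runif(length(sel)) * sum(e$rates)
        pick <- findInterval(u, cumsum(e$rates), left.open = TRUE) + 1L
        pick <- pmin(pick, length(e$to))
        to <- e$to[pick]
        new_cases <- new_cases + sum(to == 4L)
        states[sel] <- to
      }
      t_rem[idx] <- t_rem[idx] - tau[hit]
    }
    active <- idx[states[idx] <= 4L]
  }
  list(states = states, new_cases = new_cases)
}
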