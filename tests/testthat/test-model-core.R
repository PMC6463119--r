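# The within-cell generator and the exact cohort-advancement step.

hr0 <- hazard_ratios(kS = 4.94, kE = 2.20, qS = 0.49, qE = 0.20)
rates0 <- c(sigma = 0.05, delta = 0.02, lambda = 0.001, mu = 0.01, nu = 0.2)

test_that("cell generator reproduces the model equations", {
  # no transitions at all
  gen <- cell_generator(c(sigma = 0, delta = 0, lambda = 0, mu = 0, nu = 0),
                        hr0)
  expect_equal(gen$G, matrix(0, 4, 4), ignore_attr = TRUE)

  # a single uptake transition
  gen <- cell_generator(c(sigma = 0.1, delta = 0, lambda = 0, mu = 0, nu = 0),
                        hr0)
  expected <- matrix(0, 4, 4)
  expected[1, 1] <- -0.1; expected[2, 1] <- 0.1
  expect_equal(gen$G, expected, ignore_attr = TRUE)

  # full rate set against a hand-expanded matrix
  gen <- cell_generator(rates0, hr0)
  hand <- matrix(0, 4, 4)
  hand[1, 1] <- -(0.01 + 0.05 + 0.001)                       # -0.061
  hand[2, 1] <- 0.05
  hand[2, 2] <- -(1.49 * 0.01 + 0.02 + 4.94 * 0.001)         # -0.03984
  hand[3, 2] <- 0.02
  hand[3, 3] <- -(1.20 * 0.01 + 2.20 * 0.001)                # -0.0142
  hand[4, 1] <- 0.001
  hand[4, 2] <- 4.94 * 0.001
  hand[4, 3] <- 2.20 * 0.001
  hand[4, 4] <- -(0.01 + 0.2)
  expect_equal(gen$G, hand, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("generator columns conserve persons up to death outflows", {
  set.seed(11)
  for (i in 1:20) {
    r <- setNames(runif(5, 0, 0.5), c("sigma", "delta", "lambda", "mu", "nu"))
    gen <- cell_generator(r, hr0)
    expect_true(all(gen$G[row(gen$G) != col(gen$G)] >= 0))
    expect_equal(colSums(gen$G), -(gen$other_death + gen$cancer_death),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("negative rates are rejected with the symbol named", {
  bad <- rates0; bad[["lambda"]] <- -1e-4
  expect_error(cell_generator(bad, hr0, year = 1999, age = 42),
               "lambda.*1999.*42")
})

test_that("advance_cell is exact for closed-form cases", {
  # no rates: nothing moves
  gen <- cell_generator(c(sigma = 0, delta = 0, lambda = 0, mu = 0, nu = 0),
                        hr0)
  out <- advance_cell(c(100, 50, 20, 5), gen)
  expect_equal(unname(out$state), c(100, 50, 20, 5))
  expect_equal(unname(out$flows), c(0, 0, 0))

  # pure mortality with q = 0: every compartment decays by exp(-mu)
  hr_eq <- hazard_ratios(kS = 4.94, kE = 2.20, qS = 0, qE = 0)
  gen <- cell_generator(c(sigma = 0, delta = 0, lambda = 0, mu = 0.1, nu = 0),
                        hr_eq)
  out <- advance_cell(c(100, 50, 20, 5), gen)
  expect_equal(unname(out$state), c(100, 50, 20, 5) * exp(-0.1),
               tolerance = 1e-12)
  expect_equal(unname(out$flows[["other_deaths"]]),
               175 * (1 - exp(-0.1)), tolerance = 1e-12)
})

test_that("advance_cell matches a fine-step RK4 integration", {
  state <- c(1000, 600, 250, 30)
  out <- advance_cell(state, cell_generator(rates0, hr0))
  oracle <- rk4_cell_oracle(state, rates0, hr0)
  expect_equal(out$state, oracle$state, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(out$flows, oracle$flows, tolerance = 1e-8, ignore_attr = TRUE)

  # a harsher cell: high mortality and case fatality
  r2 <- c(sigma = 0.3, delta = 0.15, lambda = 0.02, mu = 0.25, nu = 0.6)
  out2 <- advance_cell(state, cell_generator(r2, hr0))
  oracle2 <- rk4_cell_oracle(state, r2, hr0)
  expect_equal(out2$state, oracle2$state, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(out2$flows, oracle2$flows, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("advance_cell conserves persons and respects flux bounds", {
  set.seed(23)
  for (i in 1:25) {
    r <- setNames(runif(5, 0, 0.4), c("sigma", "delta", "lambda", "mu", "nu"))
    state <- runif(4, 0, 1e4)
    out <- advance_cell(state, cell_generator(r, hr0))
    expect_true(all(out$state >= 0))
    expect_equal(sum(state),
                 sum(out$state) + out$flows[["other_deaths"]] +
                   out$flows[["cancer_deaths"]],
                 tolerance = 1e-10)
    # incident cases cannot exceed the people ever at risk in the cell
    expect_lte(out$flows[["new_cases"]], sum(state[1:3]) + 1e-9)
  }
})

test_that("advance_year ages cohorts along characteristics", {
  g <- lc_grid(2000, 2005, a0 = 0, a_max = 10, sex = "female")
  zero <- rate_surfaces(g, 0, 0, 0, 0, 0)
  counts <- matrix(rep(c(10, 4, 2, 1), 11), 4)
  st <- population_state(2000, counts, g)

  # zero rates, no inflow: pure shift with a pooled top bin
  out <- advance_year(st, zero, hr0, inflow = 0)
  expect_equal(sum(out$state$counts), sum(counts), tolerance = 1e-12)
  expect_equal(unname(out$state$counts[, 1]), c(0, 0, 0, 0))
  expect_equal(unname(out$state$counts[, 2]), c(10, 4, 2, 1))
  expect_equal(unname(out$state$counts[, 11]), 2 * c(10, 4, 2, 1))

  # the new cohort enters as never-smokers only
  out <- advance_year(st, zero, hr0, inflow = 1000)
  expect_equal(unname(out$state$counts[, 1]), c(1000, 0, 0, 0))

  # nontrivial surfaces: strict person accounting
  set.seed(4)
  rs <- rate_surfaces(g,
                      sigma = matrix(runif(66, 0, 0.2), 6),
                      delta = matrix(runif(66, 0, 0.1), 6),
                      lambda = matrix(runif(66, 0, 0.01), 6),
                      mu = matrix(runif(66, 0, 0.1), 6),
                      nu = matrix(runif(66, 0, 0.4), 6))
  out <- advance_year(st, rs, hr0, inflow = 77)
  deaths <- sum(out$flows[c("cancer_deaths", "other_deaths"), ])
  expect_equal(sum(counts) + 77, sum(out$state$counts) + deaths,
               tolerance = 1e-10)
})

test_that("simulation errors on years without rates", {
  g <- lc_grid(2000, 2005, a0 = 0, a_max = 4, sex = "male")
  rs <- rate_surfaces(g, 0.1, 0.01, 1e-4, 0.01, 0.2)
  st <- population_state(2006, matrix(1, 4, 5),
                         lc_grid(2006, 2010, 0, 4, "male"))
  expect_error(advance_year(st, rs, hr0, 0), "no rates defined")
})

test_that("one-year simulation reduces to advance_year", {
  g <- lc_grid(2000, 2001, a0 = 0, a_max = 8, sex = "male")
  set.seed(9)
  rs <- rate_surfaces(g,
                      sigma = matrix(runif(18, 0, 0.2), 2),
                      delta = matrix(runif(18, 0, 0.1), 2),
                      lambda = matrix(runif(18, 0, 0.01), 2),
                      mu = matrix(runif(18, 0, 0.1), 2),
                      nu = 0.3)
  st <- population_state(2000, matrix(runif(36, 0, 100), 4), g)
  traj <- simulate_population(rs, hr0, st, inflow = 12)
  step <- advance_year(st, rs, hr0, inflow = 12)
  expect_equal(traj$states[, , 2], step$state$counts, ignore_attr = TRUE)
  expect_equal(traj$flows[, , 1], step$flows, ignore_attr = TRUE)
})

test_that("constant conditions drive the age profile to a fixed point", {
  # mortality rising steeply enough that the closed top bin flushes and the
  # iteration contracts well below the tolerance within the horizon
  g <- lc_grid(2000, 2150, a0 = 0, a_max = 30, sex = "male")
  rs <- rate_surfaces(g, sigma = function(t, a) 0.08 * (a >= 15),
                      delta = 0.02, lambda = function(t, a) 1e-4 * exp(0.1 * a),
                      mu = function(t, a) 0.03 * exp(0.08 * a), nu = 0.25)
  st <- population_state(2000, matrix(c(100, 0, 0, 0), 4, 31), g)
  traj <- simulate_population(rs, hr0, st, inflow = 100)
  n <- dim(traj$states)[3]
  a <- traj$states[, , n - 1]; b <- traj$states[, , n]
  expect_lt(max(abs(a - b) / pmax(abs(b), 1e-12)), 1e-8)
})

test_that("cohort survival matches the closed form when sigma = delta = 0", {
  # with no uptake and no initial S/E/L, a cohort's never-smokers decay by
  # exp(-sum(mu + lambda)) along its characteristic
  g <- lc_grid(2000, 2010, a0 = 0, a_max = 12, sex = "male")
  set.seed(31)
  lam <- matrix(runif(11 * 13, 0, 0.05), 11)
  mu <- matrix(runif(11 * 13, 0, 0.2), 11)
  rs <- rate_surfaces(g, 0, 0, lam, mu, nu = 0.3)
  st <- population_state(2000, matrix(c(1000, rep(0, 3)), 4, 13), g)
  traj <- simulate_population(rs, hr0, st, inflow = 0)
  for (k in 1:10) {       # cohort starting at age 0 in 2000
    integ <- sum(vapply(seq_len(k), function(i) mu[i, i] + lam[i, i],
                        numeric(1)))
    expect_equal(traj$states["M", k + 1, k + 1], 1000 * exp(-integ),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("raising lambda anywhere never lowers cumulative incidence", {
  g <- lc_grid(2000, 2010, a0 = 0, a_max = 15, sex = "male")
  base_lambda <- matrix(1e-3, 11, 16)
  mk <- function(lam) {
    rs <- rate_surfaces(g, sigma = 0.05, delta = 0.02, lambda = lam,
                        mu = 0.01, nu = 0.2)
    st <- population_state(2000, matrix(c(500, 300, 100, 5), 4, 16), g)
    sum(simulate_population(rs, hr0, st, 100)$flows["new_cases", , ])
  }
  base <- mk(base_lambda)
  set.seed(13)
  for (i in 1:5) {
    bumped <- base_lambda
    cell <- c(sample(11, 1), sample(16, 1))
    bumped[cell[1], cell[2]] <- bumped[cell[1], cell[2]] + 0.05
    expect_gte(mk(bumped), base - 1e-12)
  }
})
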