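# Aggregation of trajectories onto observation strata and the composite
# Poisson/binomial log-likelihood.

# small deterministic world shared by the aggregation tests
make_world <- function() {
  g <- lc_grid(2000, 2008, a0 = 0, a_max = 19, sex = "male")
  set.seed(77)
  rs <- rate_surfaces(g,
                      sigma = matrix(runif(9 * 20, 0, 0.2), 9),
                      delta = matrix(runif(9 * 20, 0, 0.1), 9),
                      lambda = matrix(runif(9 * 20, 0, 0.02), 9),
                      mu = matrix(runif(9 * 20, 0, 0.05), 9),
                      nu = 0.3)
  st <- population_state(2000, matrix(runif(80, 100, 1000), 4), g)
  traj <- simulate_population(rs, default_hazard_ratios("male"), st, 350)
  list(g = g, traj = traj)
}

empty_counts <- function() {
  data.frame(sex = character(), year = integer(), age_lo = integer(),
             age_hi = double(), count = double())
}

test_that("stratum expectations equal brute-force sums over cells", {
  w <- make_world()
  strata <- data.frame(sex = "male",
                       year = c(2000, 2003, 2007, 2005),
                       age_lo = c(0, 5, 10, 0),
                       age_hi = c(5, 10, Inf, Inf))
  obs <- list(incidence = strata, deaths = strata, other_deaths = strata,
              population = strata,
              prevalence = cbind(strata, numerator = 1, denominator = 2))
  mu <- expected_observations(w$traj, obs)
  for (i in seq_len(nrow(strata))) {
    yi <- strata$year[i] - 2000 + 1
    ages <- max(strata$age_lo[i], 0):min(strata$age_hi[i] - 1, 19)
    ai <- ages + 1
    expect_equal(mu$incidence[i],
                 sum(w$traj$flows["new_cases", ai, yi]), tolerance = 1e-12)
    expect_equal(mu$deaths[i],
                 sum(w$traj$flows["cancer_deaths", ai, yi]),
                 tolerance = 1e-12)
    expect_equal(mu$population[i],
                 sum(w$traj$states[, ai, yi]), tolerance = 1e-12)
    expect_equal(mu$prevalence[i],
                 sum(w$traj$states["S", ai, yi]) /
                   sum(w$traj$states[, ai, yi]), tolerance = 1e-12)
  }
})

test_that("single-age strata pass cell values through", {
  w <- make_world()
  strata <- data.frame(sex = "male", year = 2004, age_lo = 7, age_hi = 8)
  obs <- list(incidence = strata, deaths = strata, other_deaths = strata,
              population = strata,
              prevalence = cbind(strata, numerator = 1, denominator = 2))
  mu <- expected_observations(w$traj, obs)
  expect_equal(mu$incidence, w$traj$flows["new_cases", 8, 5],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("pooled prevalence is the population-weighted mean", {
  # two equally sized single-age groups with prevalences 0.2 and 0.4
  g <- lc_grid(2000, 2001, a0 = 0, a_max = 1, sex = "male")
  counts <- matrix(c(800, 200, 0, 0,
                     600, 400, 0, 0), 4)
  st <- population_state(2000, counts, g)
  rs <- rate_surfaces(g, 0, 0, 0, 0, 0)
  traj <- simulate_population(rs, default_hazard_ratios("male"), st, 0)
  strata <- data.frame(sex = "male", year = 2000, age_lo = 0, age_hi = 2)
  obs <- list(incidence = empty_counts(), deaths = empty_counts(),
              other_deaths = empty_counts(), population = empty_counts(),
              prevalence = cbind(strata, numerator = 1, denominator = 2))
  mu <- expected_observations(traj, obs)
  expect_equal(mu$prevalence, 0.3, tolerance = 1e-12)
})

test_that("strata outside the grid raise errors instead of extrapolating", {
  w <- make_world()
  bad_year <- data.frame(sex = "male", year = 2008, age_lo = 0, age_hi = 5)
  obs <- list(incidence = bad_year, deaths = empty_counts(),
              other_deaths = empty_counts(), population = empty_counts(),
              prevalence = data.frame(sex = character(), year = integer(),
                                      age_lo = integer(), age_hi = double(),
                                      numerator = double(),
                                      denominator = double()))
  # 2008 is a state year but not a flow year on this grid
  expect_error(expected_observations(w$traj, obs), "years outside")
  bad_age <- data.frame(sex = "male", year = 2004, age_lo = 25, age_hi = 30)
  obs$incidence <- bad_age
  expect_error(expected_observations(w$traj, obs), "ages outside")
})

test_that("likelihood terms equal their closed forms", {
  # Poisson stratum: k = 10 observed, model mean 10
  expect_equal(lcforecast:::.pois_lpmf(10, 10),
               -10 + 10 * log(10) - log(factorial(10)), tolerance = 1e-10)
  # binomial stratum: n = 100, k = 30, p = 0.3
  expect_equal(lcforecast:::.binom_lpmf(30, 100, 0.3),
               lchoose(100, 30) + 30 * log(0.3) + 70 * log(0.7),
               tolerance = 1e-10)
  # degenerate means: a zero mean is only compatible with a zero count
  expect_identical(lcforecast:::.pois_lpmf(0, 0), 0)
  expect_identical(lcforecast:::.pois_lpmf(3, 0), -Inf)
  expect_identical(lcforecast:::.binom_lpmf(0, 50, 0), 0)
  expect_identical(lcforecast:::.binom_lpmf(2, 50, 0), -Inf)
})

test_that("the log-likelihood is additive over disjoint strata", {
  g <- lc_grid(2000, 2006, a0 = 0, a_max = 9, sex = "male")
  blocks <- block_structure(g, age_edges = list(
    sigma = c(0, 10), delta = c(0, 10), lambda = c(0, 10), mu = c(0, 10),
    nu = c(0, 10)), time_block_width = 7)
  theta <- log(c(0.05, 0.02, 0.01, 0.03, 0.2))
  inputs <- model_inputs(
    population_state(2000, matrix(rep(c(400, 100, 50, 5), 10), 4), g), 300)
  hr <- default_hazard_ratios("male")
  part1 <- data.frame(sex = "male", year = 2000:2002, age_lo = 0,
                      age_hi = 10, count = c(11, 9, 14))
  part2 <- data.frame(sex = "male", year = 2003:2005, age_lo = 0,
                      age_hi = 10, count = c(12, 8, 10))
  mk_obs <- function(inc) list(incidence = inc, deaths = empty_counts(),
                               other_deaths = empty_counts(),
                               population = empty_counts(),
                               prevalence = data.frame(
                                 sex = character(), year = integer(),
                                 age_lo = integer(), age_hi = double(),
                                 numerator = double(), denominator = double()))
  ll_both <- log_likelihood(theta, mk_obs(rbind(part1, part2)), hr, blocks,
                            inputs)
  ll_split <- log_likelihood(theta, mk_obs(part1), hr, blocks, inputs) +
    log_likelihood(theta, mk_obs(part2), hr, blocks, inputs)
  expect_equal(ll_both, ll_split, tolerance = 1e-12)
})

test_that("the generating parameters are a local maximum on noiseless data", {
  g <- lc_grid(2000, 2011, a0 = 0, a_max = 29, sex = "male")
  blocks <- block_structure(g, age_edges = list(
    sigma = c(12, 30), delta = c(12, 30), lambda = c(0, 18, 30),
    mu = c(0, 30), nu = c(0, 30)), time_block_width = 12)
  theta <- log(c(0.07, 0.03, 3e-4, 1.5e-3, 8e-4, 0.2))
  names(theta) <- blocks$param_names
  sc <- blockwise_scenario(blocks, theta, births = 1e5, n_eff = 1e5,
                           seed = 5, count_age_width = 5,
                           prevalence_breaks = c(12, 20, 30))
  synth <- generate_observations(sc, noise = FALSE)
  inputs <- synth$truth$male$inputs
  hr <- default_hazard_ratios("male")
  ll0 <- log_likelihood(theta, synth$observations, hr, blocks, inputs)
  set.seed(99)
  for (i in 1:20) {
    pert <- theta + rnorm(length(theta), 0, 0.03)
    expect_lt(log_likelihood(pert, synth$observations, hr, blocks, inputs),
              ll0)
  }
})

test_that("binomial proportions are scale-invariant", {
  # doubling every compartment leaves modeled prevalence unchanged
  g <- lc_grid(2000, 2002, a0 = 0, a_max = 4, sex = "male")
  rs <- rate_surfaces(g, 0.05, 0.02, 1e-3, 0.01, 0.2)
  hr <- default_hazard_ratios("male")
  counts <- matrix(rep(c(400, 100, 50, 5), 5), 4)
  strata <- data.frame(sex = "male", year = 2001, age_lo = 0, age_hi = 5)
  obs <- list(incidence = empty_counts(), deaths = empty_counts(),
              other_deaths = empty_counts(), population = empty_counts(),
              prevalence = cbind(strata, numerator = 1, denominator = 2))
  t1 <- simulate_population(rs, hr, population_state(2000, counts, g), 100)
  t2 <- simulate_population(rs, hr, population_state(2000, 2 * counts, g),
                            200)
  expect_equal(expected_observations(t1, obs)$prevalence,
               expected_observations(t2, obs)$prevalence, tolerance = 1e-12)
})
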