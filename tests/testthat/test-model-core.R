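make_small_data <- function(seed = 1) simulate_occu("tiny", seed = seed)$data

test_that("linear predictors reduce to inverse-logit of the design product", {
  data <- make_small_data()
  m <- occu_model("additive")

  p0 <- occu_params(m, data)  # all coefficients and offsets zero
  sf <- linear_predictors(m, p0, data)
  expect_true(all(abs(sf$psi1 - 0.5) < 1e-12))
  expect_true(all(abs(sf$gamma - 0.5) < 1e-12))
  expect_true(all(abs(sf$eps - 0.5) < 1e-12))
  expect_true(all(abs(sf$p - 0.5) < 1e-12))

  # psi intercept alone fixes psi at the reference habitat with popden 0
  cov <- site_covariates(data.frame(
    site_id = c("x1", "x2", "x3"),
    habitat = c("broadleaf", "conifer", "mixed"),
    elevation = c(10, 20, 30),
    popden = c(5, 2, 8), area = "A"))
  # make site 1's standardized popden exactly 0 by centring on its value
  cov$popden_std <- cov$popden_std - cov$popden_std[1]
  y <- matrix(0L, 3, data$seasons$n_months)
  eff <- matrix(1L, 3, data$seasons$n_months)
  d3 <- occu_data(detection_history(y, eff, cov$site_id), cov, data$seasons)
  p1 <- occu_params(m, d3, beta_psi = c(qlogis(0.8), rep(0, 7)))
  sf1 <- linear_predictors(m, p1, d3)
  expect_equal(sf1$psi1[[1]], 0.8)

  # handpicked coefficients against a by-hand dot product for one site
  set.seed(42)
  bg <- rnorm(4)
  pg <- occu_params(m, d3, beta_gamma = bg)
  sfg <- linear_predictors(m, pg, d3)
  x2 <- c(1, 0, cov$elevation_std[2], cov$popden_std[2])  # origin summer
  x2w <- c(1, 1, cov$elevation_std[2], cov$popden_std[2]) # origin winter
  lab <- d3$seasons$labels[1]
  expected <- plogis(sum((if (lab == "summer") x2 else x2w) * bg))
  expect_equal(sfg$gamma[2, 1], expected, tolerance = 1e-12)
})

test_that("parameter/variant mismatches are rejected", {
  data <- make_small_data()
  m_add <- occu_model("additive")
  m_int <- occu_model("interaction_popden")
  p_add <- occu_params(m_add, data)
  expect_error(linear_predictors(m_int, p_add, data), "variant")
  expect_error(occu_params(m_add, data, beta_psi = c(1, 2)),
               "8 coefficients")
})

test_that("transition probability follows the two-term Bernoulli rule", {
  expect_equal(transition_probability(1, gamma = 0.3, eps = 0), 1)
  expect_equal(transition_probability(0, gamma = 0.3, eps = 0.9), 0.3)
  expect_equal(transition_probability(1, gamma = 0.2, eps = 0.25), 0.75)
  expect_error(transition_probability(0, gamma = 1.2, eps = 0), "0, 1")
  # iterating the recursion reaches the gamma/(gamma+eps) equilibrium
  g <- 0.23; e <- 0.41
  occ <- 0.9
  for (i in 1:500) occ <- occ * (1 - e) + (1 - occ) * g
  expect_equal(occ, g / (g + e), tolerance = 1e-10)
})

test_that("effort adjustment compounds daily detection probability", {
  expect_equal(effort_adjusted_detection(0.5, 2), 0.75)
  p <- seq(0, 1, by = 0.05)
  expect_equal(effort_adjusted_detection(p, 1), p)
  expect_equal(effort_adjusted_detection(0.1, 30), 1 - 0.9^30)
  expect_equal(effort_adjusted_detection(0.7, 0), 0)
  # nondecreasing in days and in p
  days <- 0:31
  out <- effort_adjusted_detection(0.12, days)
  expect_true(all(diff(out) >= 0))
  out_p <- effort_adjusted_detection(seq(0, 1, 0.01), 7)
  expect_true(all(diff(out_p) >= 0))
  expect_error(effort_adjusted_detection(0.5, -1), "non-negative")
})

test_that("single-site likelihoods match closed forms", {
  ssd <- single_site_data(n_seasons = 1, months_per_season = 1,
                          effort_days = 1)
  m <- occu_model("additive")
  # psi = 0.5 by zero coefficients; p daily = 0.5 via zero p-intercept,
  # one day of effort makes pstar = 0.5
  d1 <- ssd$make(1L)
  p0 <- occu_params(m, d1)
  expect_equal(marginal_log_likelihood(m, p0, d1), log(0.25))
  d0 <- ssd$make(0L)
  expect_equal(marginal_log_likelihood(m, p0, d0), log(0.75))
})

test_that("forward recursion equals exhaustive latent-state enumeration", {
  m <- occu_model("additive")
  for (seed in 1:4) {
    sim <- simulate_occu("tiny", seed = seed)
    expect_equal(marginal_log_likelihood(m, sim$truth$params, sim$data),
                 enum_loglik(m, sim$truth$params, sim$data),
                 tolerance = 1e-10)
    # also at parameter values away from the truth
    set.seed(seed + 50)
    pr <- dynocc:::unflatten_params(
      c(rnorm(24, 0, 0.8), runif(4, 0.2, 1), rnorm(8, 0, 0.5)),
      m, sim$data)
    expect_equal(marginal_log_likelihood(m, pr, sim$data),
                 enum_loglik(m, pr, sim$data), tolerance = 1e-10)
  }
  # a longer series (4 sites x 6 seasons) with missing months
  sc <- occu_scenario(n_sites = 4, n_areas = 2, n_summer = 3, n_winter = 3,
                      summer_len = 2, winter_len = 1, first = "winter",
                      beta_gamma = c(-0.5, 1, 0.3, -0.3),
                      beta_eps = c(-0.3, -1, 0.2, 0.2),
                      beta_p = c(-1, 0.2, rep(0.1, 6)),
                      effort_range = c(2, 5), miss_rate = 0.2)
  sim <- simulate_occu(sc, seed = 8)
  expect_equal(marginal_log_likelihood(m, sim$truth$params, sim$data),
               enum_loglik(m, sim$truth$params, sim$data),
               tolerance = 1e-10)
})

test_that("compiled likelihood agrees with the R reference path", {
  m <- occu_model("interaction_elevation")
  for (seed in 1:3) {
    sc <- default_scenarios()$tiny
    sc$variant <- "interaction_elevation"
    sim <- simulate_occu(sc, seed = seed)
    md <- dynocc:::make_model_data(m, sim$data)
    th <- dynocc:::uncon_from_params(sim$truth$params)
    expect_equal(dynocc:::cpp_loglik(th, md),
                 marginal_log_likelihood(m, sim$truth$params, sim$data),
                 tolerance = 1e-10)
  }
})

test_that("raising detection probability helps a history with a detection", {
  ssd <- single_site_data(n_seasons = 1, months_per_season = 1,
                          effort_days = 3)
  m <- occu_model("additive")
  d <- ssd$make(1L)
  lls <- sapply(seq(-3, 2, by = 0.5), function(b0) {
    marginal_log_likelihood(
      m, occu_params(m, d, beta_p = c(b0, rep(0, 7))), d)
  })
  expect_true(all(diff(lls) > 0))
})

test_that("latent-state draws respect detections and the Markov law", {
  m <- occu_model("additive")
  # detections in every season force z = 1
  sim <- simulate_occu("tiny", seed = 5)
  y <- sim$data$detections$y
  y[] <- 1L
  d_all <- occu_data(
    detection_history(y, pmax(sim$data$detections$effort, 1L),
                      sim$data$detections$site_ids),
    sim$data$covariates, sim$data$seasons)
  z <- sample_latent_states(m, sim$truth$params, d_all)
  expect_true(all(z == 1L))

  # with zero effort everywhere the draw is the unconditional chain
  y0 <- y; y0[] <- 0L
  eff0 <- y; eff0[] <- 0L
  d_none <- occu_data(detection_history(y0, eff0,
                                        sim$data$detections$site_ids),
                      sim$data$covariates, sim$data$seasons)
  params <- sim$truth$params
  sf <- linear_predictors(m, params, d_none)
  TT <- d_none$seasons$n_seasons
  occ <- matrix(0, nrow(y), TT)
  occ[, 1] <- sf$psi1
  for (t in 2:TT) {
    occ[, t] <- occ[, t - 1] * (1 - sf$eps[, t - 1]) +
      (1 - occ[, t - 1]) * sf$gamma[, t - 1]
  }
  set.seed(31)
  R <- 4000
  acc <- matrix(0, nrow(y), TT)
  for (r in seq_len(R)) {
    acc <- acc + sample_latent_states(m, params, d_none)
  }
  freq <- acc / R
  se <- sqrt(occ * (1 - occ) / R)
  expect_true(all(abs(freq - occ) <= 3 * se + 1e-9))
})

test_that("conditional state probability matches Bayes rule by hand", {
  ssd <- single_site_data(1, 1, 1)
  m <- occu_model("additive")
  d0 <- ssd$make(0L)
  p0 <- occu_params(m, d0)
  # psi = p* = 0.5, y = 0: P(z=1 | y) = 0.25 / 0.75 = 1/3
  marg <- dynocc:::latent_marginals(m, p0, d0)
  expect_equal(marg[1, 1], 1 / 3, tolerance = 1e-12)
  set.seed(9)
  draws <- replicate(6000, sample_latent_states(m, p0, d0)[1, 1])
  expect_lt(abs(mean(draws) - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / 6000))
})

test_that("FFBS frequencies match forward-backward marginals", {
  m <- occu_model("additive")
  sim <- simulate_occu("tiny", seed = 13)
  params <- sim$truth$params
  marg <- dynocc:::latent_marginals(m, params, sim$data)
  set.seed(100)
  R <- 4000
  acc <- matrix(0, nrow(marg), ncol(marg))
  for (r in seq_len(R)) {
    acc <- acc + sample_latent_states(m, params, sim$data)
  }
  freq <- acc / R
  se <- sqrt(marg * (1 - marg) / R)
  expect_true(all(abs(freq - marg) <= 3 * se + 1e-9))
})
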