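test_that("log posterior equals likelihood plus hand-summed prior densities", {
  m <- occu_model("additive")
  sim <- simulate_occu("tiny", seed = 21)
  data <- sim$data
  set.seed(3)
  params <- dynocc:::unflatten_params(
    c(rnorm(24, 0, 0.7), runif(4, 0.2, 1.5), rnorm(8, 0, 0.4)), m, data)
  pri <- occu_priors()

  hand <- enum_loglik(m, params, data)
  for (b in list(params$beta_psi, params$beta_gamma, params$beta_eps,
                 params$beta_p)) {
    hand <- hand + dlogis(b[1], 0, 1, log = TRUE) +
      sum(dnorm(b[-1], 0, 1, log = TRUE))
  }
  hand <- hand + sum(log(2) + dnorm(params$sd_area, log = TRUE))
  for (k in 1:4) {
    hand <- hand + sum(dnorm(params$area_offsets[, k], 0,
                             params$sd_area[k], log = TRUE))
  }
  expect_equal(log_posterior(m, params, data, pri), unname(hand),
               tolerance = 1e-10)

  # the sampler's unconstrained target differs from the natural-scale
  # density exactly by the log-scale and non-centering Jacobian
  md <- dynocc:::make_model_data(m, data, pri)
  th <- dynocc:::uncon_from_params(params)
  jac <- sum((1 + nrow(params$area_offsets)) * log(params$sd_area))
  expect_equal(dynocc:::cpp_log_target(th, md),
               log_posterior(m, params, data, pri) + jac,
               tolerance = 1e-8)
})

test_that("with no observations the posterior is the prior", {
  m <- occu_model("additive")
  sim <- simulate_occu("tiny", seed = 22)
  y <- sim$data$detections$y; y[] <- NA_integer_
  eff <- sim$data$detections$effort; eff[] <- 0L
  d0 <- occu_data(detection_history(y, eff, sim$data$detections$site_ids),
                  sim$data$covariates, sim$data$seasons)
  params <- occu_params(m, d0, sd_area = rep(0.5, 4))
  expect_equal(marginal_log_likelihood(m, params, d0), 0)
  prior_only <- log_posterior(m, params, d0)
  n_off <- length(params$area_offsets)  # areas x 4 predictors
  expect_equal(prior_only,
               4 * dlogis(0, log = TRUE) + 20 * dnorm(0, log = TRUE) +
                 4 * (log(2) + dnorm(0.5, log = TRUE)) +
                 sum(dnorm(rep(0, n_off), 0, 0.5, log = TRUE)),
               tolerance = 1e-10)
})

test_that("retained-draw accounting matches the configuration", {
  expect_equal(check_mcmc_config(3, 1e6, 1e5, 20), 135000)
  expect_equal(check_mcmc_config(2, 200, 100, 10), 20)
  expect_error(check_mcmc_config(2, 100, 100, 10), "smaller")
  expect_error(check_mcmc_config(2, 205, 100, 10), "multiple")
  set.seed(40)
  for (k in 1:10) {
    ch <- sample(1:4, 1); th <- sample(1:20, 1)
    keep <- sample(1:50, 1) * th
    burn <- sample(0:100, 1)
    expect_equal(check_mcmc_config(ch, burn + keep, burn, th),
                 ch * keep / th)
  }
})

test_that("fits are reproducible given a seed and sized as configured", {
  m <- "additive"
  sim <- simulate_occu("tiny", seed = 30)
  f1 <- dynocc(sim$data, m, chains = 2, iter = 400, burnin = 200, thin = 4,
               seed = 77)
  f2 <- dynocc(sim$data, m, chains = 2, iter = 400, burnin = 200, thin = 4,
               seed = 77)
  expect_identical(f1$draws, f2$draws)
  expect_equal(nrow(f1$draws[[1]]), 50L)
  expect_equal(length(f1$draws), 2L)
  expect_equal(f1$mcmc$retained, 100)
  s <- summary(f1)
  expect_true(all(is.finite(s$mean)))
  expect_true(all(s$upper >= s$lower))
})

test_that("split R-hat flags disagreeing chains and matches the formula", {
  set.seed(8)
  n <- 500
  c1 <- matrix(rnorm(n), ncol = 1)
  c2 <- matrix(rnorm(n), ncol = 1)
  r_same <- rhat(list(c1, c2))
  expect_lt(abs(r_same - 1), 0.05)

  r_off <- rhat(list(c1, c2 + 10))
  expect_gt(r_off, 1.5)
  expect_false(diagnose(list(c1, c2 + 10))$converged)

  # independently coded textbook split-chain formula
  split_psrf <- function(chains) {
    halves <- list()
    for (m in chains) {
      h <- floor(nrow(m) / 2)
      halves <- c(halves, list(m[1:h, 1], m[(nrow(m) - h + 1):nrow(m), 1]))
    }
    M <- length(halves); nn <- length(halves[[1]])
    means <- sapply(halves, mean)
    vars <- sapply(halves, var)
    W <- mean(vars)
    B <- nn * var(means)
    sqrt(((nn - 1) / nn * W + B / nn) / W)
  }
  c3 <- matrix(cumsum(rnorm(n, 0.01)), ncol = 1)  # drifting chain
  for (chains in list(list(c1, c2), list(c1, c3), list(c1, c2, c3))) {
    expect_equal(unname(rhat(chains)), split_psrf(chains),
                 tolerance = 1e-12)
  }
  expect_error(rhat(list(c1)), "at least 2 chains")
})

test_that("posterior summaries follow quantile arithmetic", {
  const <- rep(3.25, 40)
  s <- summarize_draws(const)
  expect_equal(s$mean, 3.25)
  expect_equal(s$sd, 0)
  expect_equal(s$lower, 3.25)
  expect_equal(s$upper, 3.25)

  x <- matrix(1:100, ncol = 1)
  s2 <- summarize_draws(x)
  expect_equal(s2$lower, unname(quantile(1:100, 0.025)))
  expect_equal(s2$upper, unname(quantile(1:100, 0.975)))
  expect_true(s2$excl_zero)  # strictly positive draws are "significant"
  expect_true(summarize_draws(abs(rnorm(200)) + 0.1)$excl_zero)
  expect_false(summarize_draws(rnorm(200))$excl_zero)
})

test_that("prior-only sampling recovers the logistic intercept prior", {
  m <- occu_model("additive")
  sim <- simulate_occu("tiny", seed = 23)
  y <- sim$data$detections$y; y[] <- NA_integer_
  eff <- sim$data$detections$effort; eff[] <- 0L
  d0 <- occu_data(detection_history(y, eff, sim$data$detections$site_ids),
                  sim$data$covariates, sim$data$seasons)
  fit <- dynocc(d0, m, chains = 2, iter = 350000, burnin = 50000,
                thin = 60, seed = 19)
  x <- as.matrix(fit)[, "psi_(Intercept)"]
  expect_gte(length(x), 10000)
  D <- suppressWarnings(ks.test(x, plogis)$statistic)
  expect_lt(D, 1.6276 / sqrt(length(x)))  # 1% critical value
  # slope prior is standard normal
  expect_lt(abs(sd(as.matrix(fit)[, "gamma_popden"]) - 1), 0.05)
})
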