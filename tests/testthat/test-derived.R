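test_that("proportion used is pinned down by certain detection", {
  m <- occu_model("additive")
  sim <- simulate_occu("tiny", seed = 41)
  data <- sim$data

  # detections in every site-season force the whole series to 1
  y <- data$detections$y; y[] <- 1L
  d_all <- occu_data(detection_history(y, pmax(data$detections$effort, 1L),
                                       data$detections$site_ids),
                     data$covariates, data$seasons)
  fit <- degenerate_fit(m, d_all, sim$truth$params)
  u <- proportion_used(fit, n_draws = 20, seed = 1)
  expect_equal(u$mean, rep(1, data$seasons$n_seasons))
  expect_equal(u$upper - u$lower, rep(0, data$seasons$n_seasons))

  # near-certain detection with no detections forces the series to 0
  y0 <- data$detections$y; y0[] <- 0L
  d_none <- occu_data(detection_history(y0, pmax(data$detections$effort, 1L),
                                        data$detections$site_ids),
                      data$covariates, data$seasons)
  p_sure <- occu_params(m, d_none,
                        beta_p = c(20, rep(0, 7)),
                        sd_area = rep(1e-6, 4))
  fit0 <- degenerate_fit(m, d_none, p_sure)
  u0 <- proportion_used(fit0, n_draws = 20, seed = 2)
  expect_lt(max(u0$mean), 1e-6)
})

test_that("strong seasonal contrast produces the summer-winter sawtooth", {
  sim <- simulate_occu("strong_seasonality", seed = 44)
  m <- occu_model("additive")
  fit <- degenerate_fit(m, sim$data, sim$truth$params, n_draws = 60)
  u <- proportion_used(fit, n_draws = 120, seed = 3)
  # compare each summer with the following winter
  s <- u$mean[u$label == "summer"]
  w <- u$mean[u$label == "winter"]
  pairs <- min(length(s), length(w))
  expect_gte(sum(s[seq_len(pairs)] > w[seq_len(pairs)]), pairs - 1)
})

test_that("response curves follow the linear predictor exactly", {
  sc <- default_scenarios()$human_avoidance
  sim <- simulate_occu(sc, seed = 45)
  m <- occu_model("interaction_popden")

  # flat when all transition slopes vanish
  p_flat <- occu_params(m, sim$data,
                        beta_gamma = c(-0.4, 0.9, 0, 0),
                        sd_area = rep(1e-6, 4))
  fit_flat <- degenerate_fit(m, sim$data, p_flat)
  rc <- response_curve(fit_flat, "colonization", "popden",
                       grid = c(-1, 0, 1))
  expect_equal(rc$mean[rc$season_label == "summer"],
               rep(plogis(-0.4), 3), tolerance = 1e-9)
  expect_equal(rc$mean[rc$season_label == "winter"],
               rep(plogis(0.5), 3), tolerance = 1e-9)

  # hand oracle with interaction terms on a 3-point grid
  bg <- c(-0.8, 1.1, -0.7, 0.4)
  p_hand <- occu_params(m, sim$data, beta_gamma = bg,
                        sd_area = rep(1e-6, 4))
  fit_hand <- degenerate_fit(m, sim$data, p_hand)
  rc2 <- response_curve(fit_hand, "colonization", "popden",
                        grid = c(-1, 0, 2))
  for (w in 0:1) {
    expected <- plogis(bg[1] + bg[2] * w + bg[3] * c(-1, 0, 2) +
                         bg[4] * w * c(-1, 0, 2))
    got <- rc2$mean[rc2$season_label == c("summer", "winter")[w + 1]]
    expect_equal(got, expected, tolerance = 1e-9)
  }
  # negative slope means a strictly decreasing posterior-mean curve
  expect_true(all(diff(rc2$mean[rc2$season_label == "summer"]) < 0))
  # raw-scale annotation inverts the standardization
  sc_pop <- attr(sim$data$covariates, "scaling")$popden
  expect_equal(rc2$x_raw,
               rc2$x_std * sc_pop[["sd"]] + sc_pop[["mean"]])

  # requesting a covariate the variant does not model is an error
  expect_error(response_curve(fit_hand, "desertion", "elevation"),
               "interaction")
  expect_error(response_curve(fit_hand, "colonization", "popden",
                              grid = c(1, 0)), "increasing")
})
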