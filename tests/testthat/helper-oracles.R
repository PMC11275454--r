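# Brute-force likelihood oracle: enumerates all 2^T latent state
# sequences per site and sums their joint probabilities directly.
# Deliberately written without the forward recursion so it can stand as an
# independent reference for marginal_log_likelihood().
enum_loglik <- function(model, params, data) {
  sf <- linear_predictors(model, params, data)
  ss <- data$seasons
  y <- data$detections$y
  TT <- ss$n_seasons
  states <- as.matrix(expand.grid(rep(list(0:1), TT)))
  total <- 0
  for (i in seq_len(nrow(y))) {
    pr <- 0
    for (r in seq_len(nrow(states))) {
      z <- unname(as.numeric(states[r, ]))
      lp <- stats::dbinom(z[1], 1, sf$psi1[i], log = TRUE)
      if (TT > 1) for (t in 2:TT) {
        p1 <- z[t - 1] * (1 - sf$eps[i, t - 1]) +
          (1 - z[t - 1]) * sf$gamma[i, t - 1]
        lp <- lp + stats::dbinom(z[t], 1, p1, log = TRUE)
      }
      for (j in seq_len(ncol(y))) {
        if (is.na(y[i, j])) next
        lp <- lp + stats::dbinom(y[i, j], 1,
                                 z[ss$month_season[j]] * sf$pstar[i, j],
                                 log = TRUE)
      }
      pr <- pr + exp(lp)
    }
    total <- total + log(pr)
  }
  total
}

# hand-built two-site dataset where site 2 is entirely unsurveyed, so the
# dataset behaves like a single-site design with chosen psi/p
single_site_data <- function(n_seasons = 1, months_per_season = 1,
                             effort_days = 1) {
  ss <- new_season_structure(
    rep(c("summer", "winter"), length.out = n_seasons),
    rep(months_per_season, n_seasons))
  J <- ss$n_months
  y <- matrix(NA_integer_, 2, J)
  eff <- matrix(0L, 2, J)
  y[1, ] <- 0L
  eff[1, ] <- effort_days
  cov <- site_covariates(data.frame(
    site_id = c("s1", "s2"),
    habitat = c("broadleaf", "broadleaf"),
    elevation = c(0, 1), popden = c(0, 1),
    area = c("A", "A")))
  list(make = function(y1) {
    y[1, ] <- y1
    occu_data(detection_history(y, eff, c("s1", "s2")), cov, ss)
  }, seasons = ss)
}

# a fitted-model stand-in whose posterior is degenerate at `params`
# (every draw identical); enough structure for the posterior summaries,
# GoF and derived-quantity code paths
degenerate_fit <- function(model, data, params, n_draws = 20) {
  flat <- dynocc:::flatten_params(params)
  m <- matrix(rep(flat, each = n_draws), n_draws, length(flat))
  colnames(m) <- dynocc:::param_names(model, data)
  dd <- dynocc:::build_design(model, data)
  nb <- ncol(dd$Xpsi) + 2L * ncol(dd$Xtrans) + ncol(dd$Xp)
  structure(list(draws = list(m, m), model = model, data = data,
                 priors = occu_priors(),
                 mcmc = list(chains = 2, iter = n_draws, burnin = 0,
                             thin = 1, retained = 2 * n_draws),
                 accept = c(NA, NA), runtime = 0,
                 param_names = colnames(m), nb = nb,
                 n_areas = dd$n_areas),
            class = "dynocc_fit")
}

expect_dataset_equal <- function(a, b) {
  expect_identical(a$detections$y, b$detections$y)
  expect_identical(a$detections$effort, b$detections$effort)
  expect_identical(a$detections$site_ids, b$detections$site_ids)
  expect_equal(a$covariates$elevation, b$covariates$elevation)
  expect_equal(a$covariates$popden, b$covariates$popden)
  expect_identical(as.character(a$covariates$habitat),
                   as.character(b$covariates$habitat))
  expect_identical(as.character(a$covariates$area),
                   as.character(b$covariates$area))
  expect_identical(a$seasons$labels, b$seasons$labels)
  expect_identical(a$seasons$months_per_season, b$seasons$months_per_season)
}
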