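#' Simulation scenario for synthetic camera-trap data
#'
#' Describes everything needed to generate a synthetic dataset from the
#' model's own generative process: study dimensions, season structure,
#' covariate generators, effort and missingness, and the true generating
#' coefficients.
#'
#' Covariates are drawn with area-level structure (areas differ in their
#' elevation and population-density means, and in habitat composition) to
#' mimic the spatial clustering of real camera-trap areas; continuous
#' covariates are standardized before entering the linear predictors, as
#' in the analysis of real data.
#'
#' @param n_sites number of camera stations.
#' @param n_areas number of areas (random-effect groups).
#' @param n_summer,n_winter,summer_len,winter_len,first season structure,
#'   see [season_structure()].
#' @param beta_psi,beta_gamma,beta_eps,beta_p generating coefficient
#'   vectors (named or positional; defaults 0, see [occu_params()]).
#' @param sd_area generating random-effect sds, length 4.
#' @param variant model variant the transition coefficients refer to.
#' @param effort_range integer range of camera-active days per surveyed
#'   month.
#' @param gap optional `c(first_month, n_months)` contiguous block of
#'   missing months applied to every site (emulating a survey gap).
#' @param miss_rate probability that any remaining site-month is missing
#'   (camera malfunction).
#' @param area_spread sd of area-level means of the raw continuous
#'   covariates (relative to a within-area sd of 1).
#' @return An object of class `occu_scenario`.
#' @export
occu_scenario <- function(n_sites = 171, n_areas = 10,
                          n_summer = 11, n_winter = 11,
                          summer_len = 6, winter_len = 4,
                          first = "winter",
                          variant = "additive",
                          beta_psi = NULL, beta_gamma = NULL,
                          beta_eps = NULL, beta_p = NULL,
                          sd_area = c(0.3, 0.3, 0.3, 0.2),
                          effort_range = c(20, 31),
                          gap = NULL, miss_rate = 0.02,
                          area_spread = 0.8) {
  if (n_sites < n_areas) stop("need at least one site per area", call. = FALSE)
  if (miss_rate < 0 || miss_rate >= 1) stop("miss_rate must be in [0, 1)",
                                            call. = FALSE)
  stopifnot(length(effort_range) == 2L, effort_range[1] >= 1,
            effort_range[2] >= effort_range[1])
  structure(list(n_sites = as.integer(n_sites),
                 n_areas = as.integer(n_areas),
                 n_summer = n_summer, n_winter = n_winter,
                 summer_len = summer_len, winter_len = winter_len,
                 first = first, variant = variant,
                 beta_psi = beta_psi, beta_gamma = beta_gamma,
                 beta_eps = beta_eps, beta_p = beta_p,
                 sd_area = sd_area, effort_range = as.integer(effort_range),
                 gap = gap, miss_rate = miss_rate,
                 area_spread = area_spread),
            class = "occu_scenario")
}

#' Named preset scenarios
#'
#' Ready-made [occu_scenario()]s used throughout the test-bench:
#' \describe{
#'   \item{paper_shape}{the full survey geometry: 171 stations in 10
#'     areas, 11 winters of 4 months alternating with 11 summers of 6
#'     months (110 survey months), a contiguous 35-month survey gap and
#'     sporadic malfunction missingness.}
#'   \item{strong_seasonality}{100 sites, 10 areas, 10 seasons, a large
#'     season contrast in colonization and desertion (colonization much
#'     higher out of winter, desertion much higher out of summer) and
#'     moderate covariate effects.}
#'   \item{null_seasonality}{as above with the season effects set to 0.}
#'   \item{human_avoidance}{interaction variant with colonization
#'     decreasing and desertion increasing in human population density.}
#'   \item{tiny}{8 sites, 2 areas, 4 short seasons; small enough for
#'     exhaustive latent-state enumeration.}
#' }
#'
#' @return named list of `occu_scenario` objects.
#' @export
default_scenarios <- function() {
  strong <- list(
    beta_psi = c(0.4, 0.3, -0.3, -0.6, -0.5, 0.2, -0.2, 0.3),
    beta_gamma = c(-1.7, 2.2, 0.5, -0.5),
    beta_eps = c(0, -2.0, -0.3, 0.5),
    beta_p = c(-3.5, -0.3, 0.2, -0.2, -0.4, 0.1, -0.1, 0.2)
  )
  list(
    paper_shape = occu_scenario(
      n_sites = 171, n_areas = 10, n_summer = 11, n_winter = 11,
      summer_len = 6, winter_len = 4, first = "winter",
      beta_psi = strong$beta_psi, beta_gamma = strong$beta_gamma,
      beta_eps = strong$beta_eps, beta_p = strong$beta_p,
      gap = c(30, 35), miss_rate = 0.03),
    strong_seasonality = occu_scenario(
      n_sites = 100, n_areas = 10, n_summer = 5, n_winter = 5,
      summer_len = 4, winter_len = 4, first = "summer",
      beta_psi = strong$beta_psi, beta_gamma = strong$beta_gamma,
      beta_eps = strong$beta_eps, beta_p = strong$beta_p,
      miss_rate = 0),
    null_seasonality = occu_scenario(
      n_sites = 100, n_areas = 10, n_summer = 5, n_winter = 5,
      summer_len = 4, winter_len = 4, first = "summer",
      beta_psi = strong$beta_psi,
      beta_gamma = c(-1.0, 0, 0.5, -0.5),
      beta_eps = c(-0.5, 0, -0.3, 0.5),
      beta_p = strong$beta_p,
      miss_rate = 0),
    human_avoidance = occu_scenario(
      n_sites = 100, n_areas = 10, n_summer = 5, n_winter = 5,
      summer_len = 4, winter_len = 4, first = "summer",
      variant = "interaction_popden",
      beta_psi = strong$beta_psi,
      beta_gamma = c(-1.2, 1.5, -0.8, 0),
      beta_eps = c(-0.5, -1.0, 0.8, 0),
      beta_p = strong$beta_p,
      miss_rate = 0),
    tiny = occu_scenario(
      n_sites = 8, n_areas = 2, n_summer = 2, n_winter = 2,
      summer_len = 2, winter_len = 1, first = "summer",
      beta_psi = c(0.4, 0.3, -0.3, -0.6, -0.5, 0.2, -0.2, 0.3),
      beta_gamma = c(-0.8, 1.2, 0.4, -0.4),
      beta_eps = c(-0.2, -1.0, -0.3, 0.4),
      beta_p = c(-1.2, -0.3, 0.2, -0.2, -0.4, 0.1, -0.1, 0.2),
      effort_range = c(3, 6), miss_rate = 0)
  )
}

#' Simulate a synthetic camera-trap dataset
#'
#' Generates a dataset from the model's generative process: covariates
#' with area-level clustering, initial use states from \eqn{\psi_{i,1}},
#' forward state transitions via [transition_probability()], monthly
#' detections as Bernoulli draws with effort-adjusted detection
#' probability, then the missingness plan (gap block and random
#' malfunction months) applied to detections and effort jointly.
#'
#' @param scenario an [occu_scenario()] or the name of a
#'   [default_scenarios()] preset.
#' @param seed integer seed; identical scenario and seed give an identical
#'   dataset.
#' @return A list of class `occu_sim` with elements `data` (an
#'   [occu_data()]) and `truth` (generating [occu_params()], realized
#'   latent states `z`, and realized [linear_predictors()] surfaces).
#' @export
simulate_occu <- function(scenario, seed = NULL) {
  if (is.character(scenario)) {
    presets <- default_scenarios()
    if (!scenario %in% names(presets)) {
      stop("unknown scenario '", scenario, "'; available: ",
           paste(names(presets), collapse = ", "), call. = FALSE)
    }
    scenario <- presets[[scenario]]
  }
  stopifnot(inherits(scenario, "occu_scenario"))
  if (!is.null(seed)) set.seed(seed)
  sc <- scenario
  ss <- season_structure(sc$n_summer, sc$n_winter, sc$summer_len,
                         sc$winter_len, sc$first)
  n <- sc$n_sites; J <- ss$n_months

  # areas of roughly equal size; area-level covariate structure
  area <- sort(rep_len(seq_len(sc$n_areas), n))
  area_ids <- sprintf("A%02d", area)
  elev_mu <- stats::rnorm(sc$n_areas, 0, sc$area_spread)
  pop_mu <- stats::rnorm(sc$n_areas, 0, sc$area_spread)
  elevation <- 1200 + 400 * (elev_mu[area] + stats::rnorm(n))
  popden <- exp(1 + 0.8 * (pop_mu[area] + stats::rnorm(n)))
  hab_alpha <- matrix(stats::rgamma(sc$n_areas * 4L, 2), sc$n_areas, 4L)
  hab_prob <- hab_alpha / rowSums(hab_alpha)
  habitat <- vapply(seq_len(n), function(i) {
    sample(habitat_levels(), 1L, prob = hab_prob[area[i], ])
  }, character(1))
  cov <- site_covariates(data.frame(
    site_id = sprintf("site%03d", seq_len(n)),
    habitat = habitat, elevation = elevation, popden = popden,
    area = area_ids, stringsAsFactors = FALSE))

  # effort first, fully surveyed; missingness applied after generation
  effort <- matrix(sample(sc$effort_range[1]:sc$effort_range[2], n * J,
                          replace = TRUE), n, J)
  y_full <- matrix(0L, n, J)
  dh <- detection_history(y_full, effort,
                          site_ids = cov$site_id)
  data0 <- occu_data(dh, cov, ss)

  model <- occu_model(sc$variant)
  offsets <- matrix(stats::rnorm(sc$n_areas * 4L, 0,
                                 rep(sc$sd_area, each = sc$n_areas)),
                    sc$n_areas, 4L)
  params <- occu_params(model, data0, sc$beta_psi, sc$beta_gamma,
                        sc$beta_eps, sc$beta_p, sc$sd_area, offsets)
  sf <- linear_predictors(model, params, data0)

  TT <- ss$n_seasons
  z <- matrix(0L, n, TT)
  z[, 1L] <- stats::rbinom(n, 1L, sf$psi1)
  if (TT > 1L) for (t in 2L:TT) {
    pr <- transition_probability(z[, t - 1L], sf$gamma[, t - 1L],
                                 sf$eps[, t - 1L])
    z[, t] <- stats::rbinom(n, 1L, pr)
  }
  y <- matrix(stats::rbinom(n * J, 1L,
                            z[, ss$month_season] * sf$pstar), n, J)

  # missingness plan: contiguous gap block, then random malfunction
  miss <- matrix(FALSE, n, J)
  if (!is.null(sc$gap)) {
    gap_cols <- sc$gap[1]:min(J, sc$gap[1] + sc$gap[2] - 1L)
    miss[, gap_cols] <- TRUE
  }
  if (sc$miss_rate > 0) {
    miss <- miss | matrix(stats::runif(n * J) < sc$miss_rate, n, J)
  }
  y[miss] <- NA_integer_
  effort[miss] <- 0L
  dh <- detection_history(y, effort, site_ids = cov$site_id)
  data <- occu_data(dh, cov, ss)

  structure(list(data = data,
                 truth = list(params = params, z = z, surfaces = sf,
                              scenario = sc)),
            class = "occu_sim")
}

#' @export
print.occu_sim <- function(x, ...) {
  cat("Simulated occupancy dataset (variant ",
      x$truth$scenario$variant, ")\n", sep = "")
  print(x$data)
  cat(sprintf("  realized true use fraction: %.3f\n", mean(x$truth$z)))
  invisible(x)
}
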