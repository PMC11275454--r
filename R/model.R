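#' Model specification for seasonal dynamic occupancy
#'
#' Fixes the linear predictors of the three model variants.  All variants
#' share
#' \deqn{\psi \sim habitat + popden + habitat{:}popden + re(area)}
#' \deqn{p \sim season + habitat + season{:}habitat + re(area)}
#' and differ only in the colonization (\eqn{\gamma}) and desertion
#' (\eqn{\varepsilon}) predictors:
#' \describe{
#'   \item{additive}{`season + elevation + popden + re(area)`}
#'   \item{interaction_popden}{`season + popden + season:popden + re(area)`}
#'   \item{interaction_elevation}{`season + elevation + season:elevation + re(area)`}
#' }
#' Categorical covariates use treatment coding with reference levels
#' broad-leaved forest (habitat) and summer (season).  The season covariate
#' of a transition is the label of its origin season, so with alternating
#' seasons the season contrast is exactly the winter-to-summer vs
#' summer-to-winter transition contrast.
#'
#' @param variant one of `"additive"`, `"interaction_popden"`,
#'   `"interaction_elevation"`.
#' @return An object of class `occu_model`.
#' @export
occu_model <- function(variant = c("additive", "interaction_popden",
                                   "interaction_elevation")) {
  variant <- match.arg(variant)
  trans_form <- switch(variant,
    additive = ~ season + elevation + popden,
    interaction_popden = ~ season * popden,
    interaction_elevation = ~ season * elevation)
  structure(list(variant = variant,
                 psi_formula = ~ habitat * popden,
                 trans_formula = trans_form,
                 p_formula = ~ season * habitat),
            class = "occu_model")
}

#' @export
print.occu_model <- function(x, ...) {
  f <- function(fm) paste(deparse(fm[[2L]]), "+ re(area)")
  cat("Dynamic occupancy model (", x$variant, " variant)\n", sep = "")
  cat("  psi   ~", f(x$psi_formula), "\n")
  cat("  gamma ~", f(x$trans_formula), "\n")
  cat("  eps   ~", f(x$trans_formula), "\n")
  cat("  p     ~", f(x$p_formula), "\n")
  invisible(x)
}

# Design matrices for one dataset under one model variant.
# Transition and detection predictors depend on site and on the season
# label only, so they are stored as stacked 2n-row matrices: rows 1..n for
# origin/current season "summer", rows n+1..2n for "winter".
build_design <- function(model, data) {
  cov <- data$covariates
  n <- nrow(cov)
  base <- data.frame(habitat = cov$habitat,
                     elevation = cov$elevation_std,
                     popden = cov$popden_std)
  season2 <- factor(rep(c("summer", "winter"), each = n),
                    levels = c("summer", "winter"))
  both <- rbind(base, base)
  both$season <- season2
  Xpsi <- stats::model.matrix(model$psi_formula, base)
  Xtrans <- stats::model.matrix(model$trans_formula, both)
  Xp <- stats::model.matrix(model$p_formula, both)
  ss <- data$seasons
  list(Xpsi = Xpsi, Xtrans = Xtrans, Xp = Xp,
       area = as.integer(cov$area), n_areas = nlevels(cov$area),
       area_levels = levels(cov$area),
       n_sites = n,
       n_seasons = ss$n_seasons,
       # 1 where the season (or origin season of a transition) is winter
       season_winter = as.integer(ss$labels == "winter"),
       trans_winter = as.integer(ss$labels[-ss$n_seasons] == "winter"))
}

#' Parameter set for a dynamic occupancy model
#'
#' Container for every parameter of a model variant applied to a dataset:
#' fixed-effect coefficient vectors for the four predictors, the four
#' random-effect standard deviations, and the realized area offsets (one
#' per area and predictor, on the logit scale).
#'
#' Unsupplied components default to zero coefficients/offsets and standard
#' deviations of 1, which is convenient for building hand-specified truth
#' in simulations.
#'
#' @param model an [occu_model()].
#' @param data an [occu_data()] (needed for design dimensions and area
#'   levels).
#' @param beta_psi,beta_gamma,beta_eps,beta_p named or unnamed numeric
#'   coefficient vectors matching the design columns.
#' @param sd_area length-4 positive vector of random-effect sds, order
#'   (psi, gamma, eps, p).
#' @param area_offsets `n_areas` x 4 matrix of logit-scale area offsets.
#' @return An object of class `occu_params`.
#' @export
occu_params <- function(model, data, beta_psi = NULL, beta_gamma = NULL,
                        beta_eps = NULL, beta_p = NULL,
                        sd_area = rep(1, 4), area_offsets = NULL) {
  dd <- build_design(model, data)
  fill <- function(b, X, what) {
    k <- ncol(X)
    if (is.null(b)) b <- numeric(k)
    if (length(b) != k) {
      stop(what, " needs ", k, " coefficients (",
           paste(colnames(X), collapse = ", "), "), got ", length(b),
           call. = FALSE)
    }
    stats::setNames(as.numeric(b), colnames(X))
  }
  if (is.null(area_offsets)) area_offsets <- matrix(0, dd$n_areas, 4L)
  area_offsets <- as.matrix(area_offsets)
  if (!all(dim(area_offsets) == c(dd$n_areas, 4L))) {
    stop("area_offsets must be ", dd$n_areas, " x 4", call. = FALSE)
  }
  if (length(sd_area) != 4L || any(sd_area <= 0)) {
    stop("sd_area must be 4 positive values", call. = FALSE)
  }
  dimnames(area_offsets) <- list(dd$area_levels,
                                 c("psi", "gamma", "eps", "p"))
  structure(list(
    variant = model$variant,
    beta_psi = fill(beta_psi, dd$Xpsi, "beta_psi"),
    beta_gamma = fill(beta_gamma, dd$Xtrans, "beta_gamma"),
    beta_eps = fill(beta_eps, dd$Xtrans, "beta_eps"),
    beta_p = fill(beta_p, dd$Xp, "beta_p"),
    sd_area = stats::setNames(as.numeric(sd_area),
                              c("psi", "gamma", "eps", "p")),
    area_offsets = area_offsets
  ), class = "occu_params")
}

# flat named-vector layout matching an occu_params object; the order is the
# one used in posterior draw matrices
param_names <- function(model, data) {
  dd <- build_design(model, data)
  c(paste0("psi_", colnames(dd$Xpsi)),
    paste0("gamma_", colnames(dd$Xtrans)),
    paste0("eps_", colnames(dd$Xtrans)),
    paste0("p_", colnames(dd$Xp)),
    paste0("sd_area[", c("psi", "gamma", "eps", "p"), "]"),
    paste0("area_", rep(c("psi", "gamma", "eps", "p"),
                        each = dd$n_areas),
           "[", rep(dd$area_levels, 4L), "]"))
}

flatten_params <- function(params) {
  c(params$beta_psi, params$beta_gamma, params$beta_eps, params$beta_p,
    params$sd_area, as.numeric(params$area_offsets))
}

unflatten_params <- function(theta, model, data) {
  dd <- build_design(model, data)
  k <- c(ncol(dd$Xpsi), ncol(dd$Xtrans), ncol(dd$Xtrans), ncol(dd$Xp))
  i <- 0L
  take <- function(m) { out <- theta[(i + 1L):(i + m)]; i <<- i + m; out }
  bp <- take(k[1]); bg <- take(k[2]); be <- take(k[3]); bd <- take(k[4])
  sd <- take(4L)
  u <- matrix(take(4L * dd$n_areas), dd$n_areas, 4L)
  occu_params(model, data, bp, bg, be, bd, sd, u)
}

#' Inverse-logit transform
#' @param x numeric vector on the logit scale.
#' @return probabilities in (0, 1).
#' @export
inv_logit <- function(x) stats::plogis(x)

#' Occupancy transition probability
#'
#' Probability that a site is used in the next primary season, given its
#' current state and the season's colonization and desertion
#' probabilities:
#' \deqn{P(z_{t+1}=1 \mid z_t) = z_t (1-\varepsilon_t) + (1-z_t)\gamma_t.}
#'
#' @param z_prev current use state, 0/1 (vectorized).
#' @param gamma colonization probability in `[0, 1]`.
#' @param eps desertion probability in `[0, 1]`.
#' @return probability of use in the next season.
#' @examples
#' transition_probability(0, gamma = 0.3, eps = 0.9)  # 0.3
#' @export
transition_probability <- function(z_prev, gamma, eps) {
  if (any(gamma < 0 | gamma > 1 | eps < 0 | eps > 1, na.rm = TRUE)) {
    stop("gamma and eps must lie in [0, 1]", call. = FALSE)
  }
  if (!all(z_prev %in% c(0, 1))) stop("z_prev must be 0 or 1", call. = FALSE)
  z_prev * (1 - eps) + (1 - z_prev) * gamma
}

#' Effort-adjusted detection probability
#'
#' Converts a per-day detection probability into the probability of at
#' least one detection over the days a camera was active in a month:
#' \deqn{p^* = 1 - (1 - p)^{days}.}
#' Computed via `expm1`/`log1p` so that long exposures (a full month at
#' moderate p pushes \eqn{p^*} very close to 1) stay accurate.
#'
#' @param p per-day detection probability in `[0, 1]`.
#' @param days non-negative number of camera-active days (vectorized).
#' @return detection probability over the month; 0 where `days = 0`.
#' @examples
#' effort_adjusted_detection(0.5, 2)  # 0.75
#' @export
effort_adjusted_detection <- function(p, days) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]", call. = FALSE)
  if (any(days < 0, na.rm = TRUE)) stop("days must be non-negative", call. = FALSE)
  out <- -expm1(days * log1p(-p))
  out[p == 1 & days > 0] <- 1
  out[days == 0] <- 0
  out
}

#' Evaluate all rate surfaces of a parameterized model
#'
#' Applies the inverse-logit linear predictors to a dataset: initial use
#' probability per site, colonization/desertion probability per site and
#' transition, per-day detection probability per site and month, and its
#' effort-adjusted version.
#'
#' @param model an [occu_model()].
#' @param params an [occu_params()] conforming to the model.
#' @param data an [occu_data()].
#' @return A list of class `rate_surfaces` with elements `psi1` (length n),
#'   `gamma`, `eps` (n x seasons-1), `p`, `pstar` (n x months).
#' @export
linear_predictors <- function(model, params, data) {
  if (!identical(params$variant, model$variant)) {
    stop("parameter set was built for variant '", params$variant,
         "', model is '", model$variant, "'", call. = FALSE)
  }
  dd <- build_design(model, data)
  n <- dd$n_sites
  a <- dd$area
  off <- params$area_offsets
  psi1 <- inv_logit(drop(dd$Xpsi %*% params$beta_psi) + off[a, 1L])

  # stacked rows: 1..n summer, n+1..2n winter
  lin2 <- function(X, beta, col) {
    l <- drop(X %*% beta) + rep(off[a, col], 2L)
    matrix(inv_logit(l), n, 2L)  # columns: summer, winter
  }
  g2 <- lin2(dd$Xtrans, params$beta_gamma, 2L)
  e2 <- lin2(dd$Xtrans, params$beta_eps, 3L)
  p2 <- lin2(dd$Xp, params$beta_p, 4L)

  TT <- dd$n_seasons
  gamma <- g2[, dd$trans_winter + 1L, drop = FALSE]
  eps <- e2[, dd$trans_winter + 1L, drop = FALSE]
  ss <- data$seasons
  month_lab <- dd$season_winter[ss$month_season] + 1L
  p <- p2[, month_lab, drop = FALSE]
  pstar <- effort_adjusted_detection(p, data$detections$effort)
  dimnames(gamma) <- dimnames(eps) <- NULL
  structure(list(psi1 = psi1, gamma = gamma, eps = eps, p = p,
                 pstar = pstar),
            class = "rate_surfaces")
}
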