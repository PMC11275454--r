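#' Prior specification
#'
#' Weakly informative regularizing priors used for all model variants:
#' standard logistic on intercepts, standard normal on slope coefficients,
#' and half-normal (a normal truncated to positive values) on the
#' random-effect standard deviations; area offsets are normal(0, sd) given
#' their scale.  The scales can be overridden.
#'
#' @param intercept_scale scale of the logistic prior on intercepts.
#' @param coef_sd standard deviation of the normal prior on slopes.
#' @param area_sd_scale scale of the half-normal prior on random-effect
#'   standard deviations.
#' @return An object of class `occu_priors`.
#' @export
occu_priors <- function(intercept_scale = 1, coef_sd = 1, area_sd_scale = 1) {
  stopifnot(intercept_scale > 0, coef_sd > 0, area_sd_scale > 0)
  structure(list(intercept_scale = intercept_scale, coef_sd = coef_sd,
                 area_sd_scale = area_sd_scale),
            class = "occu_priors")
}

#' Joint log-posterior density (up to the model's normalizing constant)
#'
#' Marginal log-likelihood plus log prior densities: logistic on the four
#' intercepts, normal on the remaining fixed coefficients, half-normal on
#' the four random-effect sds, and normal(0, sd) on each area offset.
#'
#' @param model an [occu_model()].
#' @param params an [occu_params()].
#' @param data an [occu_data()].
#' @param priors an [occu_priors()].
#' @return A finite scalar; `-Inf` only in the limit of infinite
#'   parameters.
#' @export
log_posterior <- function(model, params, data, priors = occu_priors()) {
  ll <- marginal_log_likelihood(model, params, data)
  lp <- 0
  for (b in list(params$beta_psi, params$beta_gamma, params$beta_eps,
                 params$beta_p)) {
    lp <- lp + stats::dlogis(b[1L], 0, priors$intercept_scale, log = TRUE)
    if (length(b) > 1L) {
      lp <- lp + sum(stats::dnorm(b[-1L], 0, priors$coef_sd, log = TRUE))
    }
  }
  sd <- params$sd_area
  lp <- lp + sum(log(2) + stats::dnorm(sd, 0, priors$area_sd_scale,
                                       log = TRUE))
  lp <- lp + sum(stats::dnorm(params$area_offsets, 0,
                              rep(sd, each = nrow(params$area_offsets)),
                              log = TRUE))
  out <- as.numeric(ll + lp)
  if (is.nan(out)) stop("non-finite log posterior", call. = FALSE)
  out
}

# ---- bridging between occu_params and the sampler's unconstrained vector

# model data list consumed by the C++ routines
make_model_data <- function(model, data, priors = occu_priors()) {
  dd <- build_design(model, data)
  y <- data$detections$y
  eff <- data$detections$effort
  ss <- data$seasons
  n <- nrow(y); TT <- ss$n_seasons
  zdays <- matrix(0, n, TT)
  det_any <- matrix(0L, n, TT)
  det_i <- integer(0); det_t <- integer(0); det_days <- numeric(0)
  for (t in seq_len(TT)) {
    cols <- which(ss$month_season == t)
    ysub <- y[, cols, drop = FALSE]
    esub <- eff[, cols, drop = FALSE]
    zdays[, t] <- rowSums(esub * (!is.na(ysub) & ysub == 0))
    hit <- which(!is.na(ysub) & ysub == 1, arr.ind = TRUE)
    if (nrow(hit)) {
      det_i <- c(det_i, hit[, 1L] - 1L)
      det_t <- c(det_t, rep(t - 1L, nrow(hit)))
      det_days <- c(det_days, esub[hit])
      det_any[unique(hit[, 1L]), t] <- 1L
    }
  }
  list(Xpsi = dd$Xpsi, Xtrans = dd$Xtrans, Xp = dd$Xp,
       area0 = dd$area - 1L, n_areas = dd$n_areas,
       n_seasons = TT, trans_winter = dd$trans_winter,
       season_winter = dd$season_winter,
       zdays = zdays, det_any = det_any,
       det_i = det_i, det_t = det_t, det_days = det_days,
       prior = c(priors$intercept_scale, priors$coef_sd,
                 priors$area_sd_scale))
}

# natural scale (occu_params order) -> unconstrained sampler vector
uncon_from_params <- function(params) {
  sd <- params$sd_area
  u <- sweep(params$area_offsets, 2L, sd, "/")
  c(params$beta_psi, params$beta_gamma, params$beta_eps, params$beta_p,
    log(sd), as.numeric(u))
}

# unconstrained sampler vector -> natural-scale flat vector
natural_from_uncon <- function(theta, nb, n_areas) {
  sd <- exp(theta[nb + 1:4])
  u <- matrix(theta[(nb + 5L):length(theta)], n_areas, 4L)
  c(theta[seq_len(nb)], sd, as.numeric(sweep(u, 2L, sd, "*")))
}
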