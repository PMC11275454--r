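# Per-site-season log emission terms, aggregated over the non-missing
# months of the season.  loge1[i,t] = log P(y_{i,.,t} | z_{i,t}=1),
# loge0[i,t] = 0 if no detection (and then P = 1) else -Inf.
season_emissions <- function(surfaces, data) {
  y <- data$detections$y
  eff <- data$detections$effort
  ss <- data$seasons
  n <- nrow(y); TT <- ss$n_seasons
  lp1m <- log1p(-surfaces$p)           # log(1 - p) per site-month (daily)
  loge1 <- matrix(0, n, TT)
  det_any <- matrix(FALSE, n, TT)
  for (t in seq_len(TT)) {
    cols <- which(ss$month_season == t)
    for (j in cols) {
      obs <- !is.na(y[, j])
      if (!any(obs)) next
      d <- eff[, j]
      l1mp_star <- d * lp1m[, j]       # log(1 - p*)
      zero <- obs & y[, j] == 0
      one <- obs & y[, j] == 1
      loge1[zero, t] <- loge1[zero, t] + l1mp_star[zero]
      if (any(one)) {
        loge1[one, t] <- loge1[one, t] + log(-expm1(l1mp_star[one]))
        det_any[one, t] <- TRUE
      }
    }
  }
  list(loge1 = loge1, det_any = det_any)
}

log_sum_exp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' Exact marginal log-likelihood of a dynamic occupancy model
#'
#' Computes the likelihood of the detection histories with the latent use
#' states summed out by a forward recursion over primary seasons (the
#' two-state hidden Markov chain per site).  Missing site-months
#' contribute no observation term; a site-season with a detection forces
#' the used state, and a used site with no detections contributes the
#' probability of missing it in every surveyed month.
#'
#' @param model an [occu_model()].
#' @param params an [occu_params()].
#' @param data an [occu_data()].
#' @return The total log-likelihood (sum over sites), a finite scalar for
#'   valid parameters.
#' @export
marginal_log_likelihood <- function(model, params, data) {
  sf <- linear_predictors(model, params, data)
  em <- season_emissions(sf, data)
  ll <- sum(forward_site_loglik(sf, em, data$seasons$n_seasons))
  if (!is.finite(ll)) {
    stop("non-finite log-likelihood; parameters out of numerical range",
         call. = FALSE)
  }
  ll
}

# vector of per-site log-likelihoods via the forward recursion
forward_site_loglik <- function(surfaces, em, TT) {
  loge0 <- ifelse(em$det_any, -Inf, 0)
  la1 <- log(surfaces$psi1) + em$loge1[, 1L]
  la0 <- log1p(-surfaces$psi1) + loge0[, 1L]
  if (TT > 1L) for (t in 2L:TT) {
    g <- surfaces$gamma[, t - 1L]
    e <- surfaces$eps[, t - 1L]
    n1 <- log_sum_exp2(la1 + log1p(-e), la0 + log(g)) + em$loge1[, t]
    n0 <- log_sum_exp2(la1 + log(e), la0 + log1p(-g)) + loge0[, t]
    la1 <- n1; la0 <- n0
  }
  log_sum_exp2(la1, la0)
}

#' Draw latent use states conditional on the data
#'
#' Forward-filter backward-sampling for the per-site two-state chain:
#' returns one exact draw of the latent use matrix `z` given the detection
#' histories and a parameter set.  Any site-season with an observed
#' detection is used with probability 1.
#'
#' @param model an [occu_model()].
#' @param params an [occu_params()].
#' @param data an [occu_data()].
#' @return A sites x seasons binary matrix.
#' @export
sample_latent_states <- function(model, params, data) {
  sf <- linear_predictors(model, params, data)
  em <- season_emissions(sf, data)
  ffbs_draw(sf, em, data$seasons$n_seasons)
}

# FFBS given precomputed surfaces/emissions (vectorized over sites)
ffbs_draw <- function(surfaces, em, TT) {
  n <- length(surfaces$psi1)
  loge0 <- ifelse(em$det_any, -Inf, 0)
  la1 <- matrix(0, n, TT); la0 <- matrix(0, n, TT)
  la1[, 1L] <- log(surfaces$psi1) + em$loge1[, 1L]
  la0[, 1L] <- log1p(-surfaces$psi1) + loge0[, 1L]
  if (TT > 1L) for (t in 2L:TT) {
    g <- surfaces$gamma[, t - 1L]
    e <- surfaces$eps[, t - 1L]
    la1[, t] <- log_sum_exp2(la1[, t - 1L] + log1p(-e),
                             la0[, t - 1L] + log(g)) + em$loge1[, t]
    la0[, t] <- log_sum_exp2(la1[, t - 1L] + log(e),
                             la0[, t - 1L] + log1p(-g)) + loge0[, t]
  }
  z <- matrix(0L, n, TT)
  pr1 <- 1 / (1 + exp(la0[, TT] - la1[, TT]))
  pr1[la1[, TT] == -Inf] <- 0
  z[, TT] <- as.integer(stats::runif(n) < pr1)
  if (TT > 1L) for (t in (TT - 1L):1L) {
    g <- surfaces$gamma[, t]
    e <- surfaces$eps[, t]
    znext <- z[, t + 1L]
    # P(z_t = 1 | z_{t+1}, y_{1:t}) via filtered odds times transition
    ltrans1 <- ifelse(znext == 1L, log1p(-e), log(e))
    ltrans0 <- ifelse(znext == 1L, log(g), log1p(-g))
    l1 <- la1[, t] + ltrans1
    l0 <- la0[, t] + ltrans0
    pr1 <- 1 / (1 + exp(l0 - l1))
    pr1[l1 == -Inf] <- 0
    pr1[l0 == -Inf & l1 > -Inf] <- 1
    z[, t] <- as.integer(stats::runif(n) < pr1)
  }
  z
}

# forward-filter marginal P(z_{i,t} = 1 | full history) via
# forward-backward (used for checking FFBS frequencies)
latent_marginals <- function(model, params, data) {
  sf <- linear_predictors(model, params, data)
  em <- season_emissions(sf, data)
  TT <- data$seasons$n_seasons
  n <- length(sf$psi1)
  loge0 <- ifelse(em$det_any, -Inf, 0)
  la1 <- matrix(0, n, TT); la0 <- matrix(0, n, TT)
  la1[, 1L] <- log(sf$psi1) + em$loge1[, 1L]
  la0[, 1L] <- log1p(-sf$psi1) + loge0[, 1L]
  if (TT > 1L) for (t in 2L:TT) {
    g <- sf$gamma[, t - 1L]; e <- sf$eps[, t - 1L]
    la1[, t] <- log_sum_exp2(la1[, t - 1L] + log1p(-e),
                             la0[, t - 1L] + log(g)) + em$loge1[, t]
    la0[, t] <- log_sum_exp2(la1[, t - 1L] + log(e),
                             la0[, t - 1L] + log1p(-g)) + loge0[, t]
  }
  lb1 <- matrix(0, n, TT); lb0 <- matrix(0, n, TT)
  if (TT > 1L) for (t in (TT - 1L):1L) {
    g <- sf$gamma[, t]; e <- sf$eps[, t]
    f1 <- em$loge1[, t + 1L] + lb1[, t + 1L]
    f0 <- loge0[, t + 1L] + lb0[, t + 1L]
    lb1[, t] <- log_sum_exp2(log1p(-e) + f1, log(e) + f0)
    lb0[, t] <- log_sum_exp2(log(g) + f1, log1p(-g) + f0)
  }
  l1 <- la1 + lb1; l0 <- la0 + lb0
  pr <- 1 / (1 + exp(l0 - l1))
  pr[l1 == -Inf] <- 0
  pr
}
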