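#' Fit a seasonal dynamic occupancy model
#'
#' The package's main fitting function.  Runs adaptive random-walk
#' Metropolis chains on the posterior of the chosen model variant, with
#' the latent use states marginalized out of the likelihood by the forward
#' algorithm, so only continuous parameters are sampled; latent states can
#' be recovered afterwards with [sample_latent_states()] or the
#' posterior-summary helpers ([proportion_used()], [occu_gof()]).
#'
#' `iter` counts sampler iterations per chain including the burn-in phase
#' (during which the proposal covariances and scales adapt); one iteration
#' is a full sweep over the four parameter blocks (one block per linear
#' predictor).  The number of retained draws per chain is
#' `(iter - burnin) / thin`.  The default desk-scale configuration
#' (4 chains, 2,000 retained draws each) is deliberately far smaller than
#' a production configuration such as 3 chains of a million iterations;
#' both are expressible through these arguments.
#'
#' @param data an [occu_data()] dataset.
#' @param model model variant name or an [occu_model()] object.
#' @param priors an [occu_priors()] specification.
#' @param chains number of chains (at least 2 for convergence checks).
#' @param iter total iterations per chain, including burn-in.
#' @param burnin adaptation/burn-in iterations discarded per chain.
#' @param thin thinning interval for retained draws.
#' @param seed integer seed; the fit is fully reproducible given the seed.
#' @param init optional list of per-chain unconstrained start vectors
#'   (advanced use); by default chains start from dispersed data-informed
#'   values.
#' @return An object of class `dynocc_fit` with components `draws` (list
#'   of chains, each a retained-draws x parameters matrix on the natural
#'   scale: coefficients, positive `sd_area`, realized area offsets),
#'   `model`, `data`, `priors`, `mcmc` (configuration echo) and `accept`.
#' @seealso [summary.dynocc_fit()], [diagnose()], [occu_gof()],
#'   [proportion_used()], [response_curve()]
#' @export
dynocc <- function(data, model = "additive", priors = occu_priors(),
                   chains = 4, iter = 30000, burnin = 10000, thin = 10,
                   seed = NULL, init = NULL) {
  stopifnot(inherits(data, "occu_data"))
  if (is.character(model)) model <- occu_model(model)
  stopifnot(inherits(model, "occu_model"))
  n_keep <- check_mcmc_config(chains, iter, burnin, thin) / chains
  if (!is.null(seed)) set.seed(seed)

  md <- make_model_data(model, data, priors)
  dd <- build_design(model, data)
  nb <- ncol(dd$Xpsi) + 2L * ncol(dd$Xtrans) + ncol(dd$Xp)
  d <- nb + 4L + 4L * dd$n_areas
  pn <- param_names(model, data)

  t0 <- proc.time()[["elapsed"]]
  draws <- vector("list", chains)
  accept <- numeric(chains)
  blocks <- sampler_blocks(dd)
  for (ch in seq_len(chains)) {
    th0 <- if (!is.null(init)) init[[ch]] else init_chain(md, dd, data)
    res <- cpp_sample(md, th0, as.integer(iter), as.integer(burnin),
                      as.integer(thin), blocks)
    m <- res$draws
    # transform to the natural scale: sd positive, offsets = sd * u
    nat <- t(apply(m, 1L, natural_from_uncon, nb = nb,
                   n_areas = dd$n_areas))
    colnames(nat) <- pn
    draws[[ch]] <- nat
    accept[ch] <- res$accept
  }
  structure(list(draws = draws, model = model, data = data,
                 priors = priors,
                 mcmc = list(chains = chains, iter = iter, burnin = burnin,
                             thin = thin, seed = seed,
                             retained = chains * n_keep),
                 accept = accept,
                 runtime = proc.time()[["elapsed"]] - t0,
                 param_names = pn, nb = nb, n_areas = dd$n_areas),
            class = "dynocc_fit")
}

#' Retained-draw arithmetic of an MCMC configuration
#'
#' Validates a chains/iterations/burn-in/thinning configuration and
#' returns the total number of retained posterior draws,
#' `chains * (iter - burnin) / thin`.
#'
#' @param chains,iter,burnin,thin MCMC configuration (see [dynocc()]).
#' @return Total retained draw count across chains.
#' @examples
#' check_mcmc_config(3, 1e6, 1e5, 20)  # 135000
#' @export
check_mcmc_config <- function(chains, iter, burnin, thin) {
  stopifnot(chains >= 1, iter >= 1, thin >= 1, burnin >= 0)
  if (burnin >= iter) stop("burn-in must be smaller than iter", call. = FALSE)
  if ((iter - burnin) %% thin != 0) {
    stop("(iter - burnin) must be a multiple of thin", call. = FALSE)
  }
  chains * (iter - burnin) / thin
}

# one sampler block per linear predictor: fixed coefficients, log
# random-effect scale and raw area offsets move jointly (0-based indices)
sampler_blocks <- function(dd) {
  k <- c(ncol(dd$Xpsi), ncol(dd$Xtrans), ncol(dd$Xtrans), ncol(dd$Xp))
  nb <- sum(k)
  na <- dd$n_areas
  starts <- cumsum(c(0L, k))
  lapply(1:4, function(j) {
    as.integer(c(starts[j]:(starts[j + 1L] - 1L),
                 nb + j - 1L,
                 nb + 4L + (j - 1L) * na + 0:(na - 1L)))
  })
}

# dispersed data-informed unconstrained start values for one chain
init_chain <- function(md, dd, data) {
  nb <- ncol(dd$Xpsi) + 2L * ncol(dd$Xtrans) + ncol(dd$Xp)
  kpsi <- ncol(dd$Xpsi); kg <- ncol(dd$Xtrans); kp <- ncol(dd$Xp)
  th <- stats::rnorm(nb + 4L + 4L * dd$n_areas, 0, 0.25)
  y <- data$detections$y; eff <- data$detections$effort
  obs <- !is.na(y)
  # crude daily detection rate and naive use anchor the intercepts
  rate <- sum(y == 1, na.rm = TRUE) / max(1, sum(eff[obs]))
  rate <- min(max(rate, 1e-4), 0.5)
  nu <- naive_use(data)
  if (!is.finite(nu)) nu <- 0.5
  nu <- min(max(nu, 0.05), 0.95)
  th[1L] <- stats::qlogis(nu) + stats::rnorm(1, 0, 0.3)
  th[kpsi + 2L * kg + 1L] <- stats::qlogis(rate) + stats::rnorm(1, 0, 0.3)
  # transition intercepts mildly negative: rare transitions a priori
  th[kpsi + 1L] <- -1 + stats::rnorm(1, 0, 0.4)
  th[kpsi + kg + 1L] <- -1 + stats::rnorm(1, 0, 0.4)
  # random-effect scales start small
  th[nb + 1:4] <- log(0.3) + stats::rnorm(4, 0, 0.2)
  th
}

#' @export
print.dynocc_fit <- function(x, ...) {
  cat("Dynamic occupancy fit (", x$model$variant, " variant)\n", sep = "")
  cat("  data: ", n_sites(x$data), " sites, ",
      x$data$seasons$n_seasons, " seasons\n", sep = "")
  m <- x$mcmc
  cat(sprintf("  MCMC: %d chains x %d iter (burn-in %d, thin %d) -> %d draws\n",
              m$chains, m$iter, m$burnin, m$thin, m$retained))
  cat(sprintf("  acceptance: %s; runtime %.1fs\n",
              paste(sprintf("%.2f", x$accept), collapse = "/"), x$runtime))
  r <- try(max(rhat(x)), silent = TRUE)
  if (!inherits(r, "try-error")) {
    cat(sprintf("  max split R-hat: %.3f\n", r))
  }
  invisible(x)
}

#' Stack posterior draws of all chains into one matrix
#' @param x a `dynocc_fit`.
#' @param ... unused.
#' @return draws x parameters matrix.
#' @export
as.matrix.dynocc_fit <- function(x, ...) do.call(rbind, x$draws)

#' Posterior mean coefficients
#' @param object a `dynocc_fit`.
#' @param ... unused.
#' @return named vector of posterior means for all parameters.
#' @export
coef.dynocc_fit <- function(object, ...) colMeans(as.matrix(object))

# posterior-mean parameter set as an occu_params object
posterior_mean_params <- function(fit) {
  unflatten_params(coef(fit), fit$model, fit$data)
}

#' Marginal log-likelihood at the posterior mean
#' @param object a `dynocc_fit`.
#' @param ... unused.
#' @return `logLik` object (degrees of freedom = number of sampled
#'   parameters).
#' @export
logLik.dynocc_fit <- function(object, ...) {
  ll <- marginal_log_likelihood(object$model,
                                posterior_mean_params(object),
                                object$data)
  structure(ll, df = length(object$param_names), class = "logLik")
}

#' Summarize a fitted model
#'
#' Posterior mean, sd, equal-tailed credible interval, a flag for
#' intervals that exclude zero (the significance check used for covariate
#' effects), split R-hat and effective sample size per parameter.
#'
#' @param object a `dynocc_fit`.
#' @param prob interval probability (default 0.95).
#' @param ... unused.
#' @return A data frame of class `summary.dynocc_fit`.
#' @export
summary.dynocc_fit <- function(object, prob = 0.95, ...) {
  s <- summarize_draws(object$draws, prob = prob)
  s$rhat <- rhat(object)
  s$ess <- ess(object)
  class(s) <- c("summary.dynocc_fit", "data.frame")
  attr(s, "variant") <- object$model$variant
  attr(s, "prob") <- prob
  s
}

#' @export
print.summary.dynocc_fit <- function(x, digits = 3, ...) {
  cat("Posterior summary (", attr(x, "variant"), " variant, ",
      format(100 * attr(x, "prob")), "% credible intervals)\n", sep = "")
  df <- as.data.frame(x)
  df$excl_zero <- ifelse(df$excl_zero, "*", "")
  print(format(df, digits = digits), ...)
  invisible(x)
}

#' Posterior summaries of raw draws
#'
#' Works on a single draws matrix, a list of per-chain matrices, or a bare
#' vector.  Reports posterior mean, sd, the equal-tailed `prob` interval
#' and whether the interval excludes zero.
#'
#' @param draws matrix (draws x parameters), list of such matrices, or
#'   numeric vector.
#' @param prob interval probability.
#' @return data frame with one row per parameter.
#' @export
summarize_draws <- function(draws, prob = 0.95) {
  if (is.list(draws)) draws <- do.call(rbind, draws)
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1L)
  stopifnot(nrow(draws) >= 1, prob > 0, prob < 1)
  a <- (1 - prob) / 2
  q <- t(apply(draws, 2L, stats::quantile, probs = c(a, 1 - a),
               names = FALSE))
  out <- data.frame(
    mean = colMeans(draws),
    sd = apply(draws, 2L, stats::sd),
    lower = q[, 1L],
    upper = q[, 2L],
    excl_zero = q[, 1L] > 0 | q[, 2L] < 0
  )
  rownames(out) <- colnames(draws)
  out
}

#' Posterior-predictive replicated datasets
#'
#' Draws parameter vectors from the posterior and simulates complete
#' replicated detection histories from them, preserving the observed
#' effort and missingness pattern.  Used internally by the
#' goodness-of-fit machinery and handy for visual posterior-predictive
#' checks.
#'
#' @param object a `dynocc_fit`.
#' @param nsim number of replicated datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return A list of `nsim` [occu_data()] objects.
#' @export
simulate.dynocc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  all_draws <- as.matrix(object)
  idx <- sample.int(nrow(all_draws), nsim, replace = nsim > nrow(all_draws))
  lapply(idx, function(i) {
    params <- unflatten_params(all_draws[i, ], object$model, object$data)
    replicate_dataset(object$model, params, object$data)
  })
}

# simulate y (and z) from a parameter set on the observed design,
# keeping the observed effort/missingness pattern
replicate_dataset <- function(model, params, data, return_z = FALSE) {
  sf <- linear_predictors(model, params, data)
  n <- length(sf$psi1); TT <- data$seasons$n_seasons
  z <- matrix(0L, n, TT)
  z[, 1L] <- stats::rbinom(n, 1L, sf$psi1)
  if (TT > 1L) for (t in 2L:TT) {
    pr <- transition_probability(z[, t - 1L], sf$gamma[, t - 1L],
                                 sf$eps[, t - 1L])
    z[, t] <- stats::rbinom(n, 1L, pr)
  }
  y0 <- data$detections$y
  y <- matrix(NA_integer_, n, ncol(y0))
  sm <- data$seasons$month_season
  for (j in seq_len(ncol(y0))) {
    obs <- !is.na(y0[, j])
    pr <- z[, sm[j]] * sf$pstar[, j]
    y[obs, j] <- stats::rbinom(sum(obs), 1L, pr[obs])
  }
  dh <- detection_history(y, data$detections$effort,
                          data$detections$site_ids)
  out <- occu_data(dh, data$covariates, data$seasons)
  if (return_z) attr(out, "z") <- z
  out
}
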