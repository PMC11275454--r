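#' Seasonal proportion of sites used
#'
#' Posterior series of the proportion of sites in the used state per
#' primary season.  For every posterior draw the latent use states are
#' sampled conditional on the data and summed over sites, so the series
#' reflects both parameter and state uncertainty.
#'
#' @param fit a `dynocc_fit`.
#' @param n_draws posterior draws to use (default 500).
#' @param prob credible-interval probability.
#' @param seed optional seed.
#' @return A data frame of class `occu_use_series` with columns `season`,
#'   `label`, `mean`, `lower`, `upper`.
#' @export
proportion_used <- function(fit, n_draws = 500, prob = 0.95, seed = NULL) {
  stopifnot(inherits(fit, "dynocc_fit"))
  if (!is.null(seed)) set.seed(seed)
  all_draws <- as.matrix(fit)
  if (n_draws > nrow(all_draws)) n_draws <- nrow(all_draws)
  idx <- if (n_draws == nrow(all_draws)) seq_len(n_draws) else
    sort(sample.int(nrow(all_draws), n_draws))
  data <- fit$data
  TT <- data$seasons$n_seasons
  prop <- matrix(0, n_draws, TT)
  for (k in seq_len(n_draws)) {
    params <- unflatten_params(all_draws[idx[k], ], fit$model, data)
    z <- sample_latent_states(fit$model, params, data)
    prop[k, ] <- colMeans(z)
  }
  a <- (1 - prob) / 2
  out <- data.frame(
    season = seq_len(TT),
    label = data$seasons$labels,
    mean = colMeans(prop),
    lower = apply(prop, 2L, stats::quantile, probs = a, names = FALSE),
    upper = apply(prop, 2L, stats::quantile, probs = 1 - a, names = FALSE)
  )
  class(out) <- c("occu_use_series", "data.frame")
  out
}

#' @export
plot.occu_use_series <- function(x, ...) {
  graphics::plot(x$season, x$mean, type = "n", ylim = c(0, 1),
                 xlab = "Primary season", ylab = "Proportion of sites used",
                 ...)
  graphics::polygon(c(x$season, rev(x$season)), c(x$lower, rev(x$upper)),
                    col = "grey85", border = NA)
  graphics::lines(x$season, x$mean, lwd = 2)
  graphics::points(x$season, x$mean,
                   pch = ifelse(x$label == "summer", 19, 21), bg = "white")
  graphics::legend("topright", pch = c(19, 21), pt.bg = "white",
                   legend = c("summer", "winter"), bty = "n")
  invisible(x)
}

#' Covariate response curve of colonization or desertion
#'
#' Posterior response of the colonization or desertion probability along a
#' covariate gradient, one curve per season label, evaluated at the
#' "typical area" (random offset 0) with all other covariates at their
#' standardized mean of 0.  Only meaningful for the variant whose
#' season-by-covariate interaction involves the requested covariate
#' (`interaction_popden` for `popden`, `interaction_elevation` for
#' `elevation`); the additive variant supports either covariate without an
#' interaction.
#'
#' @param fit a `dynocc_fit`.
#' @param target `"colonization"` or `"desertion"`.
#' @param covariate `"popden"` or `"elevation"`.
#' @param grid covariate grid on the standardized scale; default 50 points
#'   over the observed range.
#' @param n_draws posterior draws used (default all retained draws).
#' @param prob credible-interval probability.
#' @return A data frame of class `occu_response_curve` with columns
#'   `season_label`, `x_std`, `x_raw`, `mean`, `lower`, `upper`.
#' @export
response_curve <- function(fit, target = c("colonization", "desertion"),
                           covariate = c("popden", "elevation"),
                           grid = NULL, n_draws = NULL, prob = 0.95) {
  stopifnot(inherits(fit, "dynocc_fit"))
  target <- match.arg(target)
  covariate <- match.arg(covariate)
  variant <- fit$model$variant
  ok <- switch(variant,
    additive = TRUE,
    interaction_popden = covariate == "popden",
    interaction_elevation = covariate == "elevation")
  if (!ok) {
    stop("variant '", variant, "' has no ", covariate,
         " effect on transitions; use the matching interaction variant",
         call. = FALSE)
  }
  cov <- fit$data$covariates
  std_col <- paste0(covariate, "_std")
  if (is.null(grid)) {
    grid <- seq(min(cov[[std_col]]), max(cov[[std_col]]), length.out = 50L)
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing", call. = FALSE)
  }
  draws <- as.matrix(fit)
  if (!is.null(n_draws)) {
    if (n_draws > nrow(draws)) n_draws <- nrow(draws)
    draws <- draws[sort(sample.int(nrow(draws), n_draws)), , drop = FALSE]
  }
  prefix <- if (target == "colonization") "gamma_" else "eps_"
  cols <- grep(paste0("^", prefix), colnames(draws))
  b <- draws[, cols, drop = FALSE]
  nm <- sub(prefix, "", colnames(draws)[cols])

  pick <- function(term) {
    j <- match(term, nm)
    if (is.na(j)) 0 else b[, j]
  }
  b0 <- pick("(Intercept)")
  bw <- pick("seasonwinter")
  bx <- pick(covariate)
  bint <- pick(paste0("seasonwinter:", covariate))

  a <- (1 - prob) / 2
  sc <- attr(cov, "scaling")[[covariate]]
  rows <- lapply(c(summer = 0, winter = 1), function(w) {
    curves <- vapply(grid, function(x) {
      pr <- inv_logit(b0 + bw * w + bx * x + bint * w * x)
      c(mean(pr), stats::quantile(pr, c(a, 1 - a), names = FALSE))
    }, numeric(3))
    data.frame(
      season_label = if (w == 0) "summer" else "winter",
      x_std = grid,
      x_raw = grid * sc[["sd"]] + sc[["mean"]],
      mean = curves[1L, ], lower = curves[2L, ], upper = curves[3L, ])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "target") <- target
  attr(out, "covariate") <- covariate
  class(out) <- c("occu_response_curve", "data.frame")
  out
}

#' @export
plot.occu_response_curve <- function(x, raw_scale = TRUE, ...) {
  xs <- if (raw_scale) "x_raw" else "x_std"
  cols <- c(summer = "#D55E00", winter = "#0072B2")
  graphics::plot(range(x[[xs]]), c(0, 1), type = "n",
                 xlab = paste0(attr(x, "covariate"),
                               if (raw_scale) " (raw scale)" else
                                 " (standardized)"),
                 ylab = paste(attr(x, "target"), "probability"), ...)
  for (lab in c("summer", "winter")) {
    d <- x[x$season_label == lab, ]
    if (!nrow(d)) next
    graphics::polygon(c(d[[xs]], rev(d[[xs]])), c(d$lower, rev(d$upper)),
                      col = grDevices::adjustcolor(cols[[lab]], 0.2),
                      border = NA)
    graphics::lines(d[[xs]], d$mean, col = cols[[lab]], lwd = 2)
  }
  graphics::legend("topright", col = cols, lwd = 2,
                   legend = paste("origin", names(cols)), bty = "n")
  invisible(x)
}

#' @export
plot.dynocc_fit <- function(x, type = c("use", "response"), ...) {
  type <- match.arg(type)
  if (type == "use") {
    plot(proportion_used(x, ...))
  } else {
    plot(response_curve(x, ...))
  }
}

#' Covariate response curves via predict
#'
#' Thin wrapper around [response_curve()] so that fitted models follow the
#' familiar `predict()` idiom.
#'
#' @param object a `dynocc_fit`.
#' @param target,covariate,grid,n_draws,prob see [response_curve()].
#' @param ... unused.
#' @return see [response_curve()].
#' @export
predict.dynocc_fit <- function(object, target = "colonization",
                               covariate = "popden", grid = NULL,
                               n_draws = NULL, prob = 0.95, ...) {
  response_curve(object, target = target, covariate = covariate,
                 grid = grid, n_draws = n_draws, prob = prob)
}
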