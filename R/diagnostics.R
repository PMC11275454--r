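#' Split-chain potential scale reduction factor
#'
#' Brooks–Gelman–Rubin convergence diagnostic, computed on split chains:
#' each chain is halved, and the usual between/within variance ratio is
#' evaluated on the resulting `2 * chains` sequences, which also detects
#' non-stationarity within a chain.  Values at 1 indicate convergence;
#' the conventional rule accepts R-hat at or below 1.1.
#'
#' @param x a `dynocc_fit` or a list of draws matrices (one per chain,
#'   equal dimensions, draws x parameters).
#' @return named vector of R-hat values, one per parameter.
#' @export
rhat <- function(x) {
  chains <- chain_list(x)
  apply_chains(chains, rhat_one)
}

rhat_one <- function(m) {
  # m: draws x split-chains matrix
  n <- nrow(m)
  W <- mean(apply(m, 2L, stats::var))
  B <- n * stats::var(colMeans(m))
  if (W == 0) return(1)
  sqrt((n - 1) / n + B / (n * W))
}

#' Effective sample size
#'
#' Multi-chain effective sample size from combined autocorrelations
#' (initial monotone positive-sequence truncation).
#'
#' @param x a `dynocc_fit` or list of per-chain draws matrices.
#' @return named vector of effective sample sizes.
#' @export
ess <- function(x) {
  chains <- chain_list(x)
  apply_chains(chains, ess_one)
}

ess_one <- function(m) {
  n <- nrow(m); M <- ncol(m)
  W <- mean(apply(m, 2L, stats::var))
  if (W == 0) return(n * M)
  B <- n * stats::var(colMeans(m))
  var_plus <- (n - 1) / n * W + B / n
  max_lag <- min(n - 2L, 1000L)
  acov <- sapply(seq_len(M), function(ch) {
    a <- stats::acf(m[, ch], lag.max = max_lag, plot = FALSE,
                    type = "covariance", demean = TRUE)$acf[, 1L, 1L]
    a
  })
  rho <- 1 - (W - rowMeans(acov)[-1L]) / var_plus
  # Geyer: sum consecutive pairs while positive
  s <- 0; t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2L
  }
  ess <- n * M / (1 + 2 * s)
  min(ess, n * M)
}

chain_list <- function(x) {
  if (inherits(x, "dynocc_fit")) x <- x$draws
  if (!is.list(x)) stop("need a dynocc_fit or a list of chain matrices",
                        call. = FALSE)
  x <- lapply(x, as.matrix)
  dims <- vapply(x, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all chains must have identical dimensions", call. = FALSE)
  }
  x
}

# split each chain in half and apply f to the draws x split-chain matrix
apply_chains <- function(chains, f) {
  n <- nrow(chains[[1L]])
  if (length(chains) < 2L) {
    stop("convergence diagnostics need at least 2 chains", call. = FALSE)
  }
  if (n < 4L) stop("need at least 4 draws per chain", call. = FALSE)
  half <- n %/% 2L
  split_chains <- unlist(lapply(chains, function(m) {
    list(m[seq_len(half), , drop = FALSE],
         m[(n - half + 1L):n, , drop = FALSE])
  }), recursive = FALSE)
  p <- ncol(chains[[1L]])
  out <- vapply(seq_len(p), function(j) {
    f(sapply(split_chains, function(m) m[, j]))
  }, numeric(1))
  names(out) <- colnames(chains[[1L]])
  out
}

#' Convergence report for a fitted model
#'
#' Computes split R-hat and effective sample sizes for every sampled
#' parameter and applies the R-hat at-most-1.1 convergence rule.
#'
#' @param x a `dynocc_fit` or list of per-chain draws matrices.
#' @param rhat_limit convergence threshold (default 1.1).
#' @return An object of class `convergence_report` with elements `rhat`,
#'   `ess`, `converged` and `worst` (name of the worst-mixing parameter).
#' @export
diagnose <- function(x, rhat_limit = 1.1) {
  r <- rhat(x)
  e <- ess(x)
  structure(list(rhat = r, ess = e,
                 converged = all(r <= rhat_limit),
                 rhat_limit = rhat_limit,
                 worst = names(r)[which.max(r)]),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("Convergence: max split R-hat = %.3f (%s), min ESS = %.0f\n",
              max(x$rhat), x$worst, min(x$ess)))
  cat(if (x$converged) {
    sprintf("All %d parameters at or below the %.2f rule.\n",
            length(x$rhat), x$rhat_limit)
  } else {
    sprintf("%d of %d parameters exceed %.2f.\n",
            sum(x$rhat > x$rhat_limit), length(x$rhat), x$rhat_limit)
  })
  invisible(x)
}
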