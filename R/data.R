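#' Standardize a continuous covariate
#'
#' Centres and scales a numeric vector to mean 0 and sample standard
#' deviation 1 (denominator n - 1), the transformation applied to
#' elevation and rural human population density before model fitting.
#'
#' @param x numeric vector, length at least 2, with positive variance.
#' @return numeric vector of the same length with mean 0 and sd 1.
#' @examples
#' standardize(c(1, 2, 3))  # -1 0 1
#' @export
standardize <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values to standardize", call. = FALSE)
  if (anyNA(x)) stop("covariate contains missing values", call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0) {
    stop("degenerate covariate: zero variance, cannot standardize", call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Habitat classes recognised in covariate tables
#' @export
habitat_levels <- function() c("broadleaf", "conifer", "mixed", "human_use")

#' Monthly detection histories with sampling effort
#'
#' Bundles the site-by-month binary detection matrix with the matching
#' effort matrix (camera-active days per site-month).  Months in which a
#' site was not sampled are `NA` in `y` and must have effort 0 or `NA`.
#'
#' @param y sites x months matrix with entries 0, 1 or `NA`.
#' @param effort sites x months matrix of non-negative integer days.
#' @param site_ids character vector of unique site identifiers; defaults
#'   to the rownames of `y`.
#' @return An object of class `detection_history`.
#' @export
detection_history <- function(y, effort, site_ids = rownames(y)) {
  y <- as.matrix(y); effort <- as.matrix(effort)
  if (is.null(site_ids)) site_ids <- sprintf("site%03d", seq_len(nrow(y)))
  site_ids <- as.character(site_ids)
  if (anyDuplicated(site_ids)) {
    stop("duplicated site_id: ", site_ids[duplicated(site_ids)][1L], call. = FALSE)
  }
  if (!all(dim(y) == dim(effort))) {
    stop("detection and effort matrices must have identical dimensions ",
         "(got ", nrow(y), "x", ncol(y), " vs ",
         nrow(effort), "x", ncol(effort), ")", call. = FALSE)
  }
  if (length(site_ids) != nrow(y)) {
    stop("site_ids length does not match number of rows", call. = FALSE)
  }
  bad <- which(!(y %in% c(0, 1)) & !is.na(y))
  if (length(bad)) {
    stop("detection values must be 0, 1 or missing (offending cell: site ",
         site_ids[row(y)[bad[1L]]], ", month ", col(y)[bad[1L]], ")",
         call. = FALSE)
  }
  if (any(effort < 0, na.rm = TRUE)) stop("effort must be non-negative", call. = FALSE)
  # a missing observation means the camera was not active: force effort 0
  effort[is.na(y)] <- 0L
  bad <- which(!is.na(y) & y == 1 & effort < 1)
  if (length(bad)) {
    stop("detection with zero effort at site ", site_ids[row(y)[bad[1L]]],
         ", month ", col(y)[bad[1L]], call. = FALSE)
  }
  bad <- which(is.na(effort))
  if (length(bad)) {
    # effort unknown but y observed is inconsistent; treat the cell as missing
    stop("effort missing for an observed cell at site ",
         site_ids[row(y)[bad[1L]]], ", month ", col(y)[bad[1L]], call. = FALSE)
  }
  storage.mode(y) <- "integer"
  storage.mode(effort) <- "integer"
  dimnames(y) <- dimnames(effort) <-
    list(site_ids, sprintf("m%03d", seq_len(ncol(y))))
  structure(list(site_ids = site_ids, y = y, effort = effort),
            class = "detection_history")
}

#' Site-level covariates
#'
#' Validates the covariate table (habitat class, elevation, rural human
#' population density, area membership) and attaches standardized versions
#' of the continuous covariates.  Standardization constants are stored so
#' that model predictions can be annotated on the raw scale.
#'
#' @param df data frame with columns `site_id`, `habitat` (one of
#'   `r paste(habitat_levels(), collapse = ", ")`), `elevation`, `popden`
#'   and `area`.
#' @return An object of class `site_covariates`: the input data frame plus
#'   `elevation_std`/`popden_std` columns, with habitat and area coerced to
#'   factors and a `scaling` attribute holding means and sds.
#' @export
site_covariates <- function(df) {
  need <- c("site_id", "habitat", "elevation", "popden", "area")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("covariate table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)[need]
  df$site_id <- as.character(df$site_id)
  if (anyDuplicated(df$site_id)) {
    stop("duplicated site_id in covariates: ",
         df$site_id[duplicated(df$site_id)][1L], call. = FALSE)
  }
  bad <- setdiff(unique(as.character(df$habitat)), habitat_levels())
  if (length(bad)) {
    stop("unknown habitat label '", bad[1L], "' (allowed: ",
         paste(habitat_levels(), collapse = ", "), ")", call. = FALSE)
  }
  df$habitat <- factor(as.character(df$habitat), levels = habitat_levels())
  df$area <- factor(as.character(df$area))
  for (v in c("elevation", "popden")) {
    if (!is.numeric(df[[v]]) || anyNA(df[[v]])) {
      stop(v, " must be numeric with no missing values", call. = FALSE)
    }
  }
  df$elevation_std <- standardize(df$elevation)
  df$popden_std <- standardize(df$popden)
  attr(df, "scaling") <- list(
    elevation = c(mean = mean(df$elevation), sd = stats::sd(df$elevation)),
    popden = c(mean = mean(df$popden), sd = stats::sd(df$popden))
  )
  class(df) <- c("site_covariates", "data.frame")
  df
}

#' Assemble a complete occupancy dataset
#'
#' Cross-validates a detection history, a covariate table and a season
#' structure: the site sets must agree (same ids, same order) and the
#' number of month columns must equal the total months of the season
#' structure.
#'
#' @param detections a [detection_history()].
#' @param covariates a [site_covariates()] table.
#' @param seasons a [season_structure()].
#' @return An object of class `occu_data`.
#' @export
occu_data <- function(detections, covariates, seasons) {
  stopifnot(inherits(detections, "detection_history"),
            inherits(covariates, "site_covariates"),
            inherits(seasons, "season_structure"))
  if (!identical(detections$site_ids, covariates$site_id)) {
    stop("site ids of detections and covariates disagree", call. = FALSE)
  }
  if (ncol(detections$y) != seasons$n_months) {
    stop("shape mismatch: detection history has ", ncol(detections$y),
         " month columns but the season structure defines ",
         seasons$n_months, " months", call. = FALSE)
  }
  structure(list(detections = detections, covariates = covariates,
                 seasons = seasons),
            class = "occu_data")
}

#' @export
print.occu_data <- function(x, ...) {
  y <- x$detections$y
  obs <- !is.na(y)
  cat("Occupancy dataset: ", nrow(y), " sites in ",
      nlevels(x$covariates$area), " areas, ",
      x$seasons$n_seasons, " seasons / ", ncol(y), " months\n", sep = "")
  cat(sprintf("  observed site-months: %d of %d (%.1f%%); detections: %d\n",
              sum(obs), length(y), 100 * mean(obs), sum(y == 1, na.rm = TRUE)))
  cat(sprintf("  naive use (site-seasons with a detection): %.3f\n",
              naive_use(x)))
  invisible(x)
}

#' Naive seasonal use
#'
#' Fraction of surveyed site-seasons with at least one detection, ignoring
#' imperfect detection.  A site-season counts as surveyed if any of its
#' months was observed.
#'
#' @param data an [occu_data()] object.
#' @return A single proportion.
#' @export
naive_use <- function(data) {
  y <- data$detections$y
  sm <- data$seasons$month_season
  det <- sapply(seq_len(data$seasons$n_seasons), function(t) {
    cols <- which(sm == t)
    rowSums(y[, cols, drop = FALSE] == 1, na.rm = TRUE) > 0
  })
  surveyed <- sapply(seq_len(data$seasons$n_seasons), function(t) {
    cols <- which(sm == t)
    rowSums(!is.na(y[, cols, drop = FALSE])) > 0
  })
  sum(det[surveyed]) / sum(surveyed)
}

#' Number of sites in a dataset
#' @param data an [occu_data()] object.
#' @return integer site count.
#' @export
n_sites <- function(data) nrow(data$detections$y)
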