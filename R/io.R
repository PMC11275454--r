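#' Read an occupancy dataset from CSV files
#'
#' Reads the four-file on-disk representation of a dataset: detection
#' histories, effort, site covariates and the season table.  All files are
#' comma-separated UTF-8 with `.` as decimal separator; missing
#' detections/effort are empty fields.
#'
#' File layouts:
#' \describe{
#'   \item{detections}{`site_id,m001,m002,...` with values 0, 1 or empty.}
#'   \item{effort}{same shape, non-negative integer days or empty.}
#'   \item{covariates}{`site_id,habitat,elevation,popden,area`.}
#'   \item{seasons}{`month,season_index,season_label` with one row per
#'     global month, labels `summer`/`winter`.}
#' }
#'
#' @param detections,effort,covariates,seasons paths to the four files.
#' @return A validated [occu_data()] object.
#' @seealso [write_occu_data()]
#' @export
read_occu_data <- function(detections, effort, covariates, seasons) {
  for (f in c(detections, effort, covariates, seasons)) {
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  }
  det <- utils::read.csv(detections, check.names = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  eff <- utils::read.csv(effort, check.names = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  cov <- utils::read.csv(covariates, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  sea <- utils::read.csv(seasons, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")

  if (!identical(names(det)[1L], "site_id") ||
      !identical(names(eff)[1L], "site_id")) {
    stop("detections/effort files must start with a site_id column",
         call. = FALSE)
  }
  if (!identical(dim(det), dim(eff)) ||
      !identical(det$site_id, eff$site_id)) {
    stop("shape mismatch between detection and effort files", call. = FALSE)
  }
  to_mat <- function(d) {
    m <- as.matrix(d[-1L])
    m[m == ""] <- NA
    mode(m) <- "numeric"
    rownames(m) <- d$site_id
    m
  }
  y <- to_mat(det)
  e <- to_mat(eff)
  e[is.na(e)] <- 0

  if (!all(c("month", "season_index", "season_label") %in% names(sea))) {
    stop("season file needs columns month, season_index, season_label",
         call. = FALSE)
  }
  sea <- sea[order(sea$month), ]
  if (!identical(as.integer(sea$month), seq_len(nrow(sea)))) {
    stop("season file must cover months 1..n exactly once", call. = FALSE)
  }
  idx <- as.integer(sea$season_index)
  if (!identical(sort(unique(idx)), seq_len(max(idx))) ||
      is.unsorted(idx) || any(diff(unique(idx)) != 1L)) {
    stop("season_index must be non-decreasing consecutive integers from 1",
         call. = FALSE)
  }
  labs <- tapply(sea$season_label, idx, function(l) {
    u <- unique(l)
    if (length(u) != 1L) stop("inconsistent season_label within a season",
                              call. = FALSE)
    u
  })
  lens <- as.integer(table(idx))
  ss <- new_season_structure(as.character(labs), lens)

  dh <- detection_history(y, e)
  sc <- site_covariates(cov)
  if (ncol(y) != ss$n_months) {
    stop("shape mismatch: detection file has ", ncol(y),
         " month columns, season file defines ", ss$n_months, call. = FALSE)
  }
  occu_data(dh, sc, ss)
}

#' Write an occupancy dataset to CSV files
#'
#' Inverse of [read_occu_data()]: writes the four CSV files so that reading
#' them back reproduces the dataset exactly (doubles are written with 17
#' significant digits; missing cells become empty fields).
#'
#' @param data an [occu_data()] object.
#' @param dir output directory, created if needed.  Alternatively supply
#'   the four paths explicitly.
#' @param detections,effort,covariates,seasons output paths (default:
#'   `detections.csv` etc. inside `dir`).
#' @return Invisibly, a named character vector of the four paths written.
#' @export
write_occu_data <- function(data, dir = ".",
                            detections = file.path(dir, "detections.csv"),
                            effort = file.path(dir, "effort.csv"),
                            covariates = file.path(dir, "covariates.csv"),
                            seasons = file.path(dir, "seasons.csv")) {
  stopifnot(inherits(data, "occu_data"))
  for (p in c(detections, effort, covariates, seasons)) {
    d <- dirname(p)
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  }
  fmt_num <- function(x) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "" else format(v, digits = 17, scientific = FALSE)
    }, character(1))
    out
  }
  write_matrix <- function(m, path, na_zero_to_empty = FALSE) {
    vals <- m
    if (na_zero_to_empty) vals[is.na(data$detections$y)] <- NA
    df <- data.frame(site_id = rownames(m),
                     apply(vals, 2L, function(col) {
                       ifelse(is.na(col), "", as.character(col))
                     }),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  }
  write_matrix(data$detections$y, detections)
  write_matrix(data$detections$effort, effort, na_zero_to_empty = TRUE)

  cov <- data$covariates
  cov_out <- data.frame(site_id = cov$site_id,
                        habitat = as.character(cov$habitat),
                        elevation = fmt_num(cov$elevation),
                        popden = fmt_num(cov$popden),
                        area = as.character(cov$area),
                        stringsAsFactors = FALSE)
  utils::write.csv(cov_out, covariates, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")

  ss <- data$seasons
  sea_out <- data.frame(month = seq_len(ss$n_months),
                        season_index = ss$month_season,
                        season_label = ss$labels[ss$month_season])
  utils::write.csv(sea_out, seasons, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(c(detections = detections, effort = effort,
              covariates = covariates, seasons = seasons))
}
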