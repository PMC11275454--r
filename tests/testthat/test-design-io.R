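test_that("standardize centres and scales with the sample sd", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(standardize(c(5, 5, 5)), "degenerate")
  x <- c(10, 20, 30, 40)
  expect_equal(standardize(x), (x - mean(x)) / sd(x))
  out <- standardize(rnorm(50))
  expect_equal(mean(out), 0)
  expect_equal(sd(out), 1)
})

test_that("standardize is location-scale invariant", {
  set.seed(5)
  for (k in 1:10) {
    x <- rnorm(sample(3:40, 1), sd = runif(1, 0.1, 50))
    a <- rnorm(1, 0, 100)
    b <- runif(1, 0.01, 10)
    expect_equal(standardize(a + b * x), standardize(x), tolerance = 1e-10)
  }
})

test_that("covariate validation catches bad tables", {
  ok <- data.frame(site_id = c("a", "b", "c"),
                   habitat = c("broadleaf", "conifer", "human_use"),
                   elevation = c(100, 500, 900),
                   popden = c(1, 5, 20), area = c("A", "A", "B"))
  sc <- site_covariates(ok)
  expect_equal(mean(sc$elevation_std), 0)
  expect_equal(sd(sc$popden_std), 1)
  bad <- ok; bad$habitat[2] <- "swamp"
  expect_error(site_covariates(bad), "unknown habitat label 'swamp'")
  dup <- ok; dup$site_id[2] <- "a"
  expect_error(site_covariates(dup), "duplicated site_id")
})

test_that("detection histories enforce the effort invariants", {
  y <- matrix(c(1L, 0L, NA, 0L), 2, 2)
  eff <- matrix(c(3L, 2L, 0L, 4L), 2, 2)
  dh <- detection_history(y, eff, c("s1", "s2"))
  expect_identical(dh$effort[1, 2], 0L)  # missing cell forced to 0 effort

  eff0 <- eff; eff0[1, 1] <- 0L
  expect_error(detection_history(y, eff0, c("s1", "s2")),
               "zero effort at site s1, month 1")
  expect_error(detection_history(y, eff[, 1, drop = FALSE]),
               "identical dimensions")
  y2 <- y; y2[2, 1] <- 2L
  expect_error(detection_history(y2, eff), "must be 0, 1 or missing")
})

test_that("datasets round-trip through the CSV format exactly", {
  dir <- withr::local_tempdir()
  for (seed in c(2, 9)) {
    sim <- simulate_occu("tiny", seed = seed)
    paths <- write_occu_data(sim$data, dir)
    back <- read_occu_data(paths["detections"], paths["effort"],
                           paths["covariates"], paths["seasons"])
    expect_dataset_equal(sim$data, back)
  }
  # with a gap and random missingness the empty cells must survive
  sc <- default_scenarios()$tiny
  sc$gap <- c(2, 2); sc$miss_rate <- 0.2
  sim <- simulate_occu(sc, seed = 4)
  expect_true(anyNA(sim$data$detections$y))
  paths <- write_occu_data(sim$data, dir)
  back <- read_occu_data(paths["detections"], paths["effort"],
                         paths["covariates"], paths["seasons"])
  expect_dataset_equal(sim$data, back)
})

test_that("full-design files have one row per station and column per month", {
  dir <- withr::local_tempdir()
  sim <- simulate_occu("paper_shape", seed = 1)
  paths <- write_occu_data(sim$data, dir)
  det <- read.csv(paths["detections"], check.names = FALSE)
  expect_equal(nrow(det), 171L)
  expect_equal(ncol(det), 1L + 110L)
})

test_that("malformed file combinations raise named validation errors", {
  dir <- withr::local_tempdir()
  sim <- simulate_occu("tiny", seed = 3)
  paths <- write_occu_data(sim$data, dir)

  # a detection with zero effort names the offending cell
  d <- sim$data
  eff <- d$detections$effort
  hit <- which(d$detections$y == 1, arr.ind = TRUE)[1, ]
  eff[hit["row"], hit["col"]] <- 0L
  bad_eff <- read.csv(paths["effort"], check.names = FALSE,
                      colClasses = "character")
  bad_eff[hit["row"], hit["col"] + 1L] <- "0"
  write.csv(bad_eff, file.path(dir, "effort_bad.csv"), row.names = FALSE,
            quote = FALSE)
  expect_error(
    read_occu_data(paths["detections"], file.path(dir, "effort_bad.csv"),
                   paths["covariates"], paths["seasons"]),
    "zero effort")

  # an extra month column vs the season table is a shape mismatch
  det <- read.csv(paths["detections"], check.names = FALSE,
                  colClasses = "character")
  det$m999 <- "0"
  write.csv(det, file.path(dir, "det_wide.csv"), row.names = FALSE,
            quote = FALSE)
  effw <- read.csv(paths["effort"], check.names = FALSE,
                   colClasses = "character")
  effw$m999 <- "1"
  write.csv(effw, file.path(dir, "eff_wide.csv"), row.names = FALSE,
            quote = FALSE)
  expect_error(
    read_occu_data(file.path(dir, "det_wide.csv"),
                   file.path(dir, "eff_wide.csv"),
                   paths["covariates"], paths["seasons"]),
    "shape mismatch")
})
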