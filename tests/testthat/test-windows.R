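test_that("window counts reproduce the study's scan geometry", {
  w_task <- compute_window_starts(804, 1.5, window_spec(30, 15))
  expect_length(w_task$starts_tr, 79)
  expect_equal(w_task$width_tr, 20L)
  expect_equal(unique(diff(w_task$starts_tr)), 10L)

  w_rest <- compute_window_starts(300, 2.0, window_spec(30, 15))
  expect_length(w_rest$starts_tr, 39)
  expect_equal(w_rest$width_tr, 15L)
  # fractional 7.5-TR step realizes as alternating 8, 7 increments
  expect_equal(diff(w_rest$starts_tr), rep(c(8L, 7L), 19))

  w_one <- compute_window_starts(20, 1.5, window_spec(30, 15))
  expect_equal(w_one$starts_tr, 0L)
  expect_error(compute_window_starts(10, 1.5, window_spec(30, 15)),
               "shorter than one window")
})

test_that("closed-form window count agrees with fractional enumeration", {
  # oracle: lay windows at exact fractional positions i*step while they fit
  oracle <- function(n, tr, width_s, step_s) {
    width <- as.integer(floor(width_s / tr + 0.5))
    step <- step_s / tr
    starts <- integer(0)
    i <- 0
    while (i * step + width <= n + 1e-9) {
      starts <- c(starts, as.integer(floor(i * step + 0.5)))
      i <- i + 1
    }
    list(starts = starts, width = width)
  }
  cases <- 0
  for (tr in c(1, 1.5, 2, 2.5, 3))
    for (n in seq(25, 500, by = 7))
      for (step_s in c(10, 15, 20)) {
        o <- oracle(n, tr, 30, step_s)
        if (length(o$starts) == 0) next
        got <- compute_window_starts(n, tr, window_spec(30, step_s))
        expect_identical(got$starts_tr, o$starts)
        expect_identical(got$width_tr, o$width)
        cases <- cases + 1
      }
  expect_gt(cases, 1000)
})

test_that("fisher_z matches atanh, is odd, increasing and clipped", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z(0.5), 0.549306144334055, tolerance = 1e-12)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_equal(fisher_z(-1), -atanh(1 - 1e-7))
  expect_error(fisher_z(1.01), "within")
  expect_error(fisher_z(NaN), "within")
})

test_that("window correlation matches a brute-force Pearson + atanh oracle", {
  rs <- default_roi_set()
  x <- withr::with_seed(3, matrix(rnorm(5 * 10), 5, 10,
                                  dimnames = list(NULL, rs$roi_names)))
  ts <- roi_timeseries(x, "S01", "task", 1.5)
  z <- window_correlation(ts, 0, 5)
  # direct formula evaluation for three ROI pairs
  pearson <- function(a, b) {
    n <- length(a)
    num <- sum(a * b) - n * mean(a) * mean(b)
    den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
    num / den
  }
  for (pair in list(c(1, 2), c(3, 7), c(9, 10))) {
    r <- pearson(x[, pair[1]], x[, pair[2]])
    expect_equal(z[pair[1], pair[2]], atanh(r), tolerance = 1e-12)
    expect_equal(z[pair[2], pair[1]], z[pair[1], pair[2]])
  }
  expect_true(all(is.na(diag(z))))
})

test_that("perfectly correlated in-window signals are clipped, constants rejected", {
  rs <- default_roi_set()
  x <- withr::with_seed(4, matrix(rnorm(40 * 10), 40, 10,
                                  dimnames = list(NULL, rs$roi_names)))
  x[, 2] <- x[, 1]  # IPSr duplicates IPSl
  ts <- roi_timeseries(x, "S01", "pre_rest", 2.0)
  z <- window_correlation(ts, 0, 20)
  expect_equal(z[1, 2], atanh(1 - 1e-7))
  x2 <- withr::with_seed(5, matrix(rnorm(40 * 10), 40, 10,
                                   dimnames = list(NULL, rs$roi_names)))
  x2[12:31, 4] <- 7  # PCC flat exactly in the window starting at TR 11
  ts2 <- roi_timeseries(x2, "S01", "pre_rest", 2.0)
  expect_error(window_correlation(ts2, 11, 20), "PCC")
})

test_that("white-noise null z-values concentrate near zero", {
  rs <- default_roi_set()
  width <- 200
  z_off <- withr::with_seed(6, {
    x <- matrix(rnorm(width * 10), width, 10,
                dimnames = list(NULL, rs$roi_names))
    ts <- roi_timeseries(x, "S01", "task", 1.5)
    z <- window_correlation(ts, 0, width)
    z[lower.tri(z)]
  })
  # sd(z) ~ 1/sqrt(width - 3); 4-sigma bound on each of 45 nulls
  expect_true(all(abs(z_off) < 4 / sqrt(width - 3)))
  expect_lt(abs(mean(z_off)), 3 / sqrt(45 * (width - 3)) * 3)
})

test_that("sliding_window_fc windows whole scans in order", {
  cohort <- small_cohort(seed = 21, n_subjects = 2)
  ts <- cohort$scans[[1]]  # pre_rest, 120 volumes at TR 2
  wfc <- sliding_window_fc(ts)
  expect_s3_class(wfc, "windowed_fc")
  expect_length(wfc$windows, length(compute_window_starts(120, 2)$starts_tr))
  expect_true(all(diff(wfc$starts_tr) > 0))
  feats <- fc_features(wfc)
  expect_equal(dim(feats), c(length(wfc$windows), 45))
  # each row is the vectorized window matrix
  expect_equal(feats[3, ], vectorize_upper_triangle(wfc$windows[[3]]),
               ignore_attr = TRUE)
})

test_that("stationary single-state windows converge to the planted z-matrix", {
  bps <- default_blueprints()
  sim <- simulate_scan(bps, n_volumes = 4000, tr_seconds = 2.0,
                       occupancy_profile = c(0, 0, 1, 0, 0),
                       subject_id = "S01", condition = "pre_rest",
                       ar_coef = 0, seed = 31)
  # long windows: sampling noise ~ 1/sqrt(497) per feature
  z <- window_correlation(sim$ts, 0, 500)
  target <- suppressWarnings(atanh(bps[[3]]$correlation))
  diag(target) <- NA
  err <- abs(z - target)
  expect_lt(max(err, na.rm = TRUE), 4.5 / sqrt(497))
})
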