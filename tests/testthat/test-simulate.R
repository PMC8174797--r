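test_that("blueprints realize the documented qualitative state structure", {
  bps <- default_blueprints()
  expect_length(bps, 5)
  rs <- default_roi_set()
  net <- rs$network_of
  inter <- outer(net, net, "!=")
  intra <- !inter & !diag(10)

  z3 <- bps[[3]]$z
  expect_true(all(abs(z3[inter]) <= 0.05))
  expect_true(all(z3[intra] >= 0.6, na.rm = TRUE))

  z5 <- bps[[5]]$z
  dmn <- names(net)[net == "DMN"]
  others <- names(net)[net != "DMN"]
  dan <- names(net)[net == "DAN"]
  fpn <- names(net)[net == "FPN"]
  expect_true(all(z5[dmn, others] < 0))
  expect_true(all(z5[dan, fpn] > 0))
  # DMN intra-network coupling is the strongest across all states
  dmn_intra_mean <- vapply(bps, function(b)
    mean(b$z[dmn, dmn], na.rm = TRUE), numeric(1))
  expect_equal(which.max(dmn_intra_mean), 5L)

  z4 <- bps[[4]]$z
  left_fpn <- c("LPFCl", "pPCl"); right_fpn <- c("LPFCr", "pPCr")
  expect_true(all(z4[right_fpn, dmn] >= 0.6))
  expect_true(all(z4[left_fpn, dan] >= 0.6))
  expect_true(all(abs(z4[left_fpn, right_fpn]) <= 0.05))

  z1 <- bps[[1]]$z
  expect_true(all(abs(z1["MPFC", c(dan, fpn)]) <= 0.05))
  expect_true(all(z1["MPFC", setdiff(dmn, "MPFC")] >= 0.6))
})

test_that("blueprints are mutually distinguishable and PD with small repair", {
  bps <- default_blueprints()
  feats <- blueprint_features(bps)
  r <- stats::cor(t(feats))
  expect_true(all(r[upper.tri(r)] < 0.8))
  for (b in bps) {
    expect_lt(b$repair_delta, 0.05)
    ev <- eigen(b$correlation, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    expect_equal(unname(diag(b$correlation)), rep(1, 10), tolerance = 1e-12)
  }
  # mutually anticorrelated levels are far from any correlation matrix
  z_bad <- matrix(atanh(-0.9), 10, 10,
                  dimnames = list(default_roi_set()$roi_names,
                                  default_roi_set()$roi_names))
  diag(z_bad) <- NA
  expect_error(state_blueprint(1, z_bad), "repair")
})

test_that("scan simulation is deterministic and carries exact ground truth", {
  bps <- default_blueprints()
  a <- simulate_scan(bps, 200, 2.0, rep(0.2, 5), "S01", "pre_rest",
                     seed = 10)
  b <- simulate_scan(bps, 200, 2.0, rep(0.2, 5), "S01", "pre_rest",
                     seed = 10)
  expect_identical(a$ts$data, b$ts$data)
  expect_identical(a$truth$states, b$truth$states)
  expect_equal(a$truth$occupancy,
               tabulate(a$truth$states, 5) / 200, tolerance = 1e-15)
  c_ <- simulate_scan(bps, 200, 2.0, rep(0.2, 5), "S01", "pre_rest",
                      seed = 11)
  expect_false(identical(a$ts$data, c_$ts$data))
})

test_that("the hidden chain is ergodic with the planted stationary law", {
  labels <- simulate_window_labels(1e5, rep(0.2, 5), seed = 12)
  freqs <- tabulate(labels, 5) / 1e5
  expect_true(all(abs(freqs - 0.2) < 0.02))
  # dwell calibration: mean run length close to the requested 3 steps
  runs <- rle(labels)
  expect_equal(mean(runs$lengths), 3, tolerance = 0.25)
})

test_that("a single-state scan clusters onto its own blueprint", {
  bps <- default_blueprints()
  sim <- simulate_scan(bps, 804, 1.5, c(0, 0, 1, 0, 0), "S01", "task",
                       seed = 13)
  expect_true(all(sim$truth$states == 3L))
  feats <- fc_features(sliding_window_fc(sim$ts))
  labels <- assign_windows(blueprint_features(bps), feats)
  expect_gt(mean(labels == 3L), 0.9)
})

test_that("long single-state scans converge to the planted covariance", {
  bps <- default_blueprints()
  sim <- simulate_scan(bps, 1e5, 2.0, c(0, 0, 0, 0, 1), "S01", "pre_rest",
                       seed = 14)
  emp <- stats::cov(sim$ts$data)
  target <- bps[[5]]$correlation
  rel_err <- norm(emp - target, "F") / norm(target, "F")
  expect_lt(rel_err, 0.05)
})

test_that("the default cohort realizes the study design", {
  design <- cohort_design()
  expect_equal(unname(design$occupancy_profiles["pre_rest", 3]), 0.381,
               tolerance = 0.01)
  cohort <- simulate_cohort(cohort_design(seed = 15))
  expect_equal(nrow(cohort$manifest), 44)
  expect_equal(unname(table(cohort$manifest$condition)[
    c("pre_rest", "task", "post_rest")]), c(15L, 15L, 14L),
    ignore_attr = TRUE)
  expect_false("S15_post_rest" %in% cohort$manifest$scan_id)

  full <- simulate_cohort(cohort_design(
    seed = 16, n_subjects = 3,
    conditions = list(pre_rest = c(100, 2.0), task = c(120, 1.5)),
    missing_cells = data.frame(subject = character(),
                               condition = character())))
  expect_equal(nrow(full$manifest), 6)
})
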