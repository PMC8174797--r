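# Synthetic multi-subject cohort with hidden connectivity-state dynamics.

# Transition matrix with stationary distribution `profile` and mean dwell
# `dwell` (in the same time unit as the chain): P = (1-a) I + a 1 pi', whose
# stationary law is pi and whose occupancy-weighted mean leave rate is
# a (1 - sum(pi^2)); a is calibrated so the average dwell equals `dwell`.
markov_transition <- function(profile, dwell) {
  stopifnot(all(profile >= 0), abs(sum(profile) - 1) < 1e-8, dwell > 0)
  a <- min(1, 1 / (dwell * (1 - sum(profile^2))))
  k <- length(profile)
  (1 - a) * diag(k) + a * matrix(profile, k, k, byrow = TRUE)
}

sample_chain <- function(n, transition, profile) {
  k <- length(profile)
  s <- integer(n)
  s[1L] <- sample.int(k, 1L, prob = profile)
  for (t in 2L:n)
    s[t] <- sample.int(k, 1L, prob = transition[s[t - 1L], ])
  s
}

#' Simulate a hidden state label sequence
#'
#' Draws window labels from a Markov chain whose stationary distribution is
#' `profile` and whose mean dwell time is `dwell_mean_windows` window steps.
#' Used directly for occupancy-level simulation studies (calibration and
#' power of the mixed-model test) without generating ROI signals.
#'
#' @param n_windows sequence length.
#' @param profile state probability vector.
#' @param dwell_mean_windows mean dwell in window steps.
#' @param seed RNG seed.
#' @return Integer label vector of length `n_windows`.
#' @export
simulate_window_labels <- function(n_windows, profile,
                                   dwell_mean_windows = 3, seed) {
  trans <- markov_transition(profile, dwell_mean_windows)
  withr::with_seed(seed, sample_chain(n_windows, trans, profile))
}

#' Simulate one scan's ROI time series from planted state dynamics
#'
#' A hidden state sequence is drawn per TR from a Markov chain whose
#' stationary distribution equals `occupancy_profile`; the mean dwell is
#' `dwell_mean_windows` window-equivalents, converted to TRs via the window
#' step. Observations are zero-mean Gaussian draws with the active state's
#' (positive-definite repaired) blueprint correlation as covariance, then
#' AR(1)-smoothed per ROI with unit-variance-preserving weights, the simplest
#' temporal structure under which windowed Pearson correlation consistently
#' estimates the planted pattern.
#'
#' @param blueprints list of `state_blueprint`s.
#' @param n_volumes scan length in TRs.
#' @param tr_seconds repetition time.
#' @param occupancy_profile state probability vector.
#' @param subject_id,condition scan metadata.
#' @param dwell_mean_windows mean state dwell in window-step units.
#' @param ar_coef AR(1) smoothing coefficient in `[0, 1)`.
#' @param step_seconds window step used to convert dwell to TRs.
#' @param seed RNG seed; the scan is a deterministic function of it.
#' @param roi_set the [roi_set()].
#' @return List with `ts` (an [roi_timeseries()]) and `truth` (list with
#'   `states` per TR, `occupancy` = planted per-scan state frequencies).
#' @export
simulate_scan <- function(blueprints, n_volumes, tr_seconds,
                          occupancy_profile, subject_id, condition,
                          dwell_mean_windows = 3, ar_coef = 0.3,
                          step_seconds = 15, seed,
                          roi_set = default_roi_set()) {
  k <- length(blueprints)
  stopifnot(length(occupancy_profile) == k, ar_coef >= 0, ar_coef < 1)
  dwell_tr <- dwell_mean_windows * step_seconds / tr_seconds
  trans <- markov_transition(occupancy_profile, dwell_tr)
  chols <- lapply(blueprints, function(b) chol(b$correlation))
  withr::with_seed(seed, {
    states <- sample_chain(n_volumes, trans, occupancy_profile)
    x <- matrix(stats::rnorm(n_volumes * 10L), n_volumes, 10L)
    runs <- rle(states)
    at <- 1L
    for (r_ in seq_along(runs$lengths)) {
      len <- runs$lengths[r_]
      rows <- at:(at + len - 1L)
      x[rows, ] <- x[rows, , drop = FALSE] %*% chols[[runs$values[r_]]]
      at <- at + len
    }
  })
  if (ar_coef > 0) {
    y <- x
    w <- sqrt(1 - ar_coef^2)
    for (t in 2L:n_volumes)
      y[t, ] <- ar_coef * y[t - 1L, ] + w * x[t, ]
    x <- y
  }
  colnames(x) <- roi_set$roi_names
  ts <- roi_timeseries(x, subject_id = subject_id, condition = condition,
                       tr_seconds = tr_seconds, roi_set = roi_set)
  list(ts = ts,
       truth = list(states = states,
                    occupancy = tabulate(states, k) / n_volumes))
}

#' Cohort design: subjects, conditions, planted occupancy profiles
#'
#' Defaults emulate a 15-subject, three-condition study: pre-task rest
#' (300 volumes, TR 2.0 s), a focused-attention task (804 volumes, TR 1.5 s)
#' and post-task rest (300 volumes, TR 2.0 s), with the last subject missing
#' the post-task scan. The default planted occupancy profiles shift mass out
#' of the low-connectivity state 3 and into state 4 during the task relative
#' to rest.
#'
#' @param n_subjects number of subjects.
#' @param conditions named list of `c(n_volumes, tr_seconds)` per condition.
#' @param missing_cells data frame (`subject`, `condition`) of absent scans.
#' @param occupancy_profiles matrix (condition x state) of planted state
#'   probabilities; rows must sum to 1.
#' @param dwell_mean_windows mean state dwell in window steps.
#' @param ar_coef AR(1) smoothing coefficient.
#' @param seed master seed for cohort generation.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_subjects = 15L,
                          conditions = list(pre_rest = c(300, 2.0),
                                            task = c(804, 1.5),
                                            post_rest = c(300, 2.0)),
                          missing_cells = NULL,
                          occupancy_profiles = NULL,
                          dwell_mean_windows = 3,
                          ar_coef = 0.3,
                          seed = 20210528L) {
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  if (is.null(missing_cells))
    missing_cells <- data.frame(subject = subjects[n_subjects],
                                condition = "post_rest")
  if (is.null(occupancy_profiles)) {
    occupancy_profiles <- rbind(
      pre_rest  = c(0.172, 0.140, 0.381, 0.138, 0.167),
      task      = c(0.172, 0.188, 0.251, 0.221, 0.165),
      post_rest = c(0.168, 0.188, 0.294, 0.153, 0.194))
    occupancy_profiles <- occupancy_profiles[names(conditions), ,
                                             drop = FALSE]
  }
  occupancy_profiles <- occupancy_profiles / rowSums(occupancy_profiles)
  stopifnot(all(occupancy_profiles >= 0),
            nrow(occupancy_profiles) == length(conditions),
            all(missing_cells$condition %in% names(conditions)),
            all(missing_cells$subject %in% subjects))
  structure(list(subjects = subjects, conditions = conditions,
                 missing_cells = missing_cells,
                 occupancy_profiles = occupancy_profiles,
                 dwell_mean_windows = dwell_mean_windows,
                 ar_coef = ar_coef, seed = seed),
            class = "cohort_design")
}

#' Simulate a full multi-subject cohort with ground truth
#'
#' Generates one scan per present (subject, condition) cell of the design;
#' every scan's RNG stream is derived deterministically from the design seed.
#'
#' @param design a [cohort_design()].
#' @param blueprints list of `state_blueprint`s (default
#'   [default_blueprints()]).
#' @param spec the [window_spec()] whose step calibrates dwell times.
#' @return An object of class `dfc_cohort`: `scans` (named list of
#'   [roi_timeseries()]), `manifest` (data frame), `truth` (named list of
#'   per-scan ground truth).
#' @export
simulate_cohort <- function(design = cohort_design(),
                            blueprints = default_blueprints(),
                            spec = window_spec()) {
  stopifnot(inherits(design, "cohort_design"))
  grid <- expand.grid(subject = design$subjects,
                      condition = names(design$conditions),
                      stringsAsFactors = FALSE)
  drop <- paste(design$missing_cells$subject,
                design$missing_cells$condition)
  grid <- grid[!(paste(grid$subject, grid$condition) %in% drop), ]
  grid <- grid[order(grid$subject, match(grid$condition,
                                         names(design$conditions))), ]
  seeds <- derive_seeds(design$seed, nrow(grid))
  scans <- vector("list", nrow(grid))
  truth <- vector("list", nrow(grid))
  ids <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cond <- grid$condition[i]
    pars <- design$conditions[[cond]]
    sim <- simulate_scan(blueprints,
                         n_volumes = pars[1L], tr_seconds = pars[2L],
                         occupancy_profile =
                           design$occupancy_profiles[cond, ],
                         subject_id = grid$subject[i], condition = cond,
                         dwell_mean_windows = design$dwell_mean_windows,
                         ar_coef = design$ar_coef,
                         step_seconds = spec$step_seconds,
                         seed = seeds[i])
    ids[i] <- paste(grid$subject[i], cond, sep = "_")
    scans[[i]] <- sim$ts
    truth[[i]] <- sim$truth
  }
  names(scans) <- ids
  names(truth) <- ids
  manifest <- data.frame(scan_id = ids, subject = grid$subject,
                         condition = grid$condition,
                         tr_seconds = vapply(grid$condition, function(cn)
                           design$conditions[[cn]][2L], numeric(1L)),
                         n_volumes = vapply(grid$condition, function(cn)
                           design$conditions[[cn]][1L], numeric(1L)))
  rownames(manifest) <- NULL
  structure(list(scans = scans, manifest = manifest, truth = truth,
                 design = design,
                 blueprints = blueprints),
            class = "dfc_cohort")
}
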