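#' Fit dynamic functional-connectivity states to a cohort
#'
#' The package's central estimator. Every scan is windowed with the given
#' sliding-window specification; per-window Fisher-z connectivity matrices are
#' pooled across scans into one group dataset; the number of states is chosen
#' by the majority rule over a panel of cluster-validity indices (or fixed by
#' the caller); states are estimated by seeded k-means; and each window is
#' classified to its nearest state, yielding per-scan fractional occupancies.
#'
#' The result is a deterministic function of the cohort, the configuration and
#' the seed.
#'
#' @param cohort a `dfc_cohort` (from [simulate_cohort()] or [read_cohort()]),
#'   or a list of [roi_timeseries()] objects.
#' @param window a [window_spec()].
#' @param k `"auto"` for majority-rule selection, or a fixed integer.
#' @param k_range candidate k values when `k = "auto"`.
#' @param n_init,max_iter k-means restarts and Lloyd iterations.
#' @param seed master seed; all stochastic stages derive their streams from
#'   it.
#' @param index_set validity indices for `k = "auto"` (see
#'   [select_k_majority()]).
#' @return An object of class `dfc_states` with components `solution` (a
#'   `state_solution`), `k_selection` (or `NULL` when k was fixed),
#'   `occupancy` (an [occupancy_table()]), `features`, `index` (window-level
#'   provenance), `windowed`, `manifest`, `window`, `seed`, `call`.
#' @examples
#' design <- cohort_design(n_subjects = 3,
#'                         conditions = list(pre_rest = c(120, 2),
#'                                           task = c(150, 1.5)),
#'                         missing_cells = data.frame(subject = character(),
#'                                                    condition = character()),
#'                         occupancy_profiles = NULL, seed = 1)
#' \donttest{
#' cohort <- simulate_cohort(design)
#' fit <- dfc_states(cohort, k = 5, seed = 1)
#' summary(fit)
#' }
#' @export
dfc_states <- function(cohort, window = window_spec(), k = "auto",
                       k_range = 2:8, n_init = 25L, max_iter = 25L,
                       seed = 20210528L,
                       index_set = c("silhouette", "ch", "db", "dunn",
                                     "hartigan", "ball_hall", "elbow",
                                     "gap")) {
  cohort <- as_dfc_cohort(cohort)
  cw <- cohort_windows(cohort, window)
  sub <- derive_seeds(seed, 2L)
  ksel <- NULL
  if (identical(k, "auto")) {
    ksel <- select_k_majority(cw$features, k_range = k_range,
                              index_set = index_set, seed = sub[1L])
    k <- ksel$chosen_k
  }
  k <- as.integer(k)
  sol <- kmeans_states(cw$features, k, seed = sub[2L], n_init = n_init,
                       max_iter = max_iter)
  labels <- split(sol$assignments, match(cw$index$scan_id,
                                         cohort$manifest$scan_id))
  labels <- labels[as.character(seq_len(nrow(cohort$manifest)))]
  occ <- occupancy_table(labels, cohort$manifest, k = k)
  structure(list(solution = sol, k_selection = ksel, occupancy = occ,
                 features = cw$features, index = cw$index,
                 windowed = cw$windowed, labels = labels,
                 manifest = cohort$manifest, window = window,
                 seed = seed, call = match.call()),
            class = "dfc_states")
}

as_dfc_cohort <- function(x) {
  if (inherits(x, "dfc_cohort")) return(x)
  if (is.list(x) && all(vapply(x, inherits, logical(1L), "roi_timeseries"))) {
    ids <- vapply(x, function(ts) paste(ts$subject_id, ts$condition,
                                        sep = "_"), character(1L))
    names(x) <- ids
    manifest <- data.frame(
      scan_id = ids,
      subject = vapply(x, `[[`, character(1L), "subject_id"),
      condition = vapply(x, `[[`, character(1L), "condition"),
      tr_seconds = vapply(x, `[[`, numeric(1L), "tr_seconds"),
      n_volumes = vapply(x, function(ts) nrow(ts$data), numeric(1L)))
    rownames(manifest) <- NULL
    return(structure(list(scans = x, manifest = manifest, truth = NULL),
                     class = "dfc_cohort"))
  }
  stop("cohort must be a dfc_cohort or a list of roi_timeseries")
}

#' @export
print.dfc_states <- function(x, ...) {
  cat(sprintf("DFC state fit: k = %d states over %d windows (%d scans)\n",
              x$solution$k, nrow(x$features), nrow(x$manifest)))
  if (!is.null(x$k_selection))
    cat(sprintf("  k chosen by majority rule (%d of %d index votes)\n",
                max(x$k_selection$votes), sum(x$k_selection$votes)))
  cat(sprintf("  window: %g s width / %g s step; seed %d\n",
              x$window$width_seconds, x$window$step_seconds, x$seed))
  invisible(x)
}

#' @export
summary.dfc_states <- function(object, ...) {
  occ <- object$occupancy
  mean_occ <- tapply(occ$proportion, list(occ$condition, occ$state), mean)
  win_counts <- tapply(object$index$window, object$index$condition, length)
  out <- list(k = object$solution$k, n_windows = nrow(object$features),
              windows_by_condition = win_counts,
              mean_occupancy = mean_occ, sizes = object$solution$sizes,
              inertia = object$solution$inertia,
              k_selection = object$k_selection)
  class(out) <- "summary.dfc_states"
  out
}

#' @export
print.summary.dfc_states <- function(x, digits = 3, ...) {
  cat(sprintf("DFC state fit: k = %d, %d windows (%s)\n", x$k, x$n_windows,
              paste(names(x$windows_by_condition), x$windows_by_condition,
                    sep = " = ", collapse = ", ")))
  cat("Mean fractional occupancy (condition x state):\n")
  print(round(x$mean_occupancy, digits))
  cat("State sizes:", paste(x$sizes, collapse = ", "),
      sprintf("; inertia %.4g\n", x$inertia))
  if (!is.null(x$k_selection)) print(x$k_selection)
  invisible(x)
}

#' @export
coef.dfc_states <- function(object, as_matrix = FALSE, ...) {
  if (!as_matrix) return(object$solution$centroids)
  state_centroid_matrices(object$solution,
                          roi_names = colnames(object$windowed[[1L]]$windows[[1L]]))
}

#' @export
fitted.dfc_states <- function(object, ...) object$solution$assignments

#' @export
residuals.dfc_states <- function(object, ...) {
  object$features -
    object$solution$centroids[object$solution$assignments, , drop = FALSE]
}

#' Classify new windows with a fitted state solution
#'
#' @param object a `dfc_states` fit.
#' @param newdata a `dfc_cohort`, an [roi_timeseries()], a `windowed_fc`, or
#'   a feature matrix; omitted, returns the training assignments.
#' @param ... unused.
#' @return Integer state labels.
#' @export
predict.dfc_states <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$solution$assignments)
  feats <-
    if (is.matrix(newdata)) newdata
    else if (inherits(newdata, "windowed_fc")) fc_features(newdata)
    else if (inherits(newdata, "roi_timeseries"))
      fc_features(sliding_window_fc(newdata, object$window))
    else if (inherits(newdata, "dfc_cohort"))
      cohort_windows(newdata, object$window)$features
    else stop("unsupported newdata type")
  assign_windows(object$solution, feats)
}

#' Heatmaps of the fitted state centroids
#'
#' @param x a `dfc_states` fit.
#' @param zlim symmetric colour range for the z-values.
#' @param ... unused.
#' @export
plot.dfc_states <- function(x, zlim = NULL, ...) {
  mats <- coef(x, as_matrix = TRUE)
  if (is.null(zlim)) {
    m <- max(abs(unlist(mats)), na.rm = TRUE)
    zlim <- c(-m, m)
  }
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  old <- graphics::par(mfrow = c(1, length(mats)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (s in seq_along(mats)) {
    m <- mats[[s]]
    graphics::image(seq_len(nrow(m)), seq_len(ncol(m)),
                    t(m[rev(seq_len(nrow(m))), ]), zlim = zlim, col = pal,
                    axes = FALSE, xlab = "", ylab = "",
                    main = paste("State", s))
    graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                   cex.axis = 0.6)
    graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                   las = 2, cex.axis = 0.6)
  }
  invisible(x)
}

#' Run the full state pipeline and write its artifacts
#'
#' End-to-end orchestration: fit the state model, test condition-by-state
#' occupancy differences, and write centroids (TSV matrices), window
#' assignments, the occupancy and transition tables, the statistical report
#' (JSON mirroring statistic / df / raw p / adjusted p / d / CI) and a
#' structured log with per-stage counts to a run directory. Re-running with
#' the same cohort and configuration reproduces every artifact.
#'
#' @param cohort a `dfc_cohort`.
#' @param out_dir output directory.
#' @param k,window,seed,n_init,max_iter passed to [dfc_states()].
#' @param family_size Bonferroni family for the post hoc contrasts.
#' @return Invisibly, list with `fit` (the `dfc_states` object) and `lme`
#'   (the `occupancy_lme` report).
#' @export
run_dfc_pipeline <- function(cohort, out_dir, k = "auto",
                             window = window_spec(), seed = 20210528L,
                             n_init = 25L, max_iter = 25L, family_size = 5L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "",
                                file = log_path, append = TRUE)
  cat("", file = log_path)
  log_line("stage=windows scans=%d", nrow(cohort$manifest))
  fit <- dfc_states(cohort, window = window, k = k, seed = seed,
                    n_init = n_init, max_iter = max_iter)
  counts <- tapply(fit$index$window, fit$index$condition, length)
  log_line("stage=windows %s total=%d",
           paste(names(counts), counts, sep = "=", collapse = " "),
           nrow(fit$features))
  log_line("stage=cluster k=%d inertia=%.6g seed=%d", fit$solution$k,
           fit$solution$inertia, seed)
  roi_names <- colnames(fit$windowed[[1L]]$windows[[1L]])
  mats <- coef(fit, as_matrix = TRUE)
  for (s in seq_along(mats)) {
    m <- mats[[s]]
    utils::write.table(round(m, 10), file.path(out_dir,
                                               sprintf("centroid_state%d.tsv",
                                                       s)),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  assign_df <- cbind(fit$index, state = fit$solution$assignments)
  utils::write.table(assign_df, file.path(out_dir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(fit$occupancy),
                     file.path(out_dir, "occupancy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  trans <- do.call(rbind, lapply(seq_along(fit$labels), function(i) {
    tc <- transition_counts(fit$labels[[i]], k = fit$solution$k)
    df <- as.data.frame(as.table(tc$counts))
    names(df) <- c("from", "to", "count")
    cbind(scan_id = fit$manifest$scan_id[i], df)
  }))
  utils::write.table(trans, file.path(out_dir, "transitions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  lme <- fit_occupancy_lme(fit$occupancy, family_size = family_size)
  report <- list(
    interaction = lme$interaction,
    contrasts = lme$contrasts,
    sigma = lme$sigma,
    family_size = family_size,
    k = fit$solution$k,
    seed = seed,
    window = unclass(fit$window))
  jsonlite::write_json(report, file.path(out_dir, "lme_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  log_line("stage=stats interaction_F=%.6g p=%.6g", lme$interaction$F,
           lme$interaction$p)
  invisible(list(fit = fit, lme = lme))
}

#' Compare the states of two pipeline runs
#'
#' Formats [match_states()] output for two fits (e.g. individual- versus
#' atlas-parcellation runs): the optimal pairing with per-pair correlation,
#' p-value and confidence interval.
#'
#' @param run_a,run_b `dfc_states` fits (or `state_solution`s) with equal k.
#' @param ci_level confidence level.
#' @return A `state_matching`.
#' @export
compare_parcellations <- function(run_a, run_b, ci_level = 0.95) {
  sol_a <- if (inherits(run_a, "dfc_states")) run_a$solution else run_a
  sol_b <- if (inherits(run_b, "dfc_states")) run_b$solution else run_b
  match_states(sol_a, sol_b, ci_level = ci_level)
}
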