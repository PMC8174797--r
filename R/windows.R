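#' Sliding-window specification
#'
#' Window geometry is stated in seconds and converted to repetition-time (TR)
#' units per scan, so that scans acquired with different TRs share the same
#' temporal window. Defaults are a 30-s width with 15-s steps, the minimum
#' width generally recommended for capturing connectivity fluctuations.
#'
#' @param width_seconds window width in seconds (> 0).
#' @param step_seconds step between consecutive window starts in seconds,
#'   no larger than the width.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(width_seconds = 30, step_seconds = 15) {
  if (!(is.numeric(width_seconds) && is.numeric(step_seconds) &&
        step_seconds > 0 && width_seconds >= step_seconds))
    stop("need width_seconds >= step_seconds > 0")
  structure(list(width_seconds = width_seconds, step_seconds = step_seconds),
            class = "window_spec")
}

round_half_up <- function(x) floor(x + 0.5)

#' Window start indices for a scan
#'
#' Converts the window spec to TR units and places windows with exact
#' fractional-TR stepping: the width is `round(width_seconds / tr)` TRs, the
#' i-th window (i = 0, 1, ...) starts at TR `round(i * step_seconds / tr)`
#' (half-up rounding), and windows are laid as long as they fit. With a
#' fractional step, integer starts alternate (e.g. a 7.5-TR step realizes as
#' increments 8, 7, 8, 7, ...), which is the only placement consistent with
#' obtaining 39 windows from a 300-volume, TR 2 s scan and 79 windows from an
#' 804-volume, TR 1.5 s scan under the default 30 s / 15 s spec.
#'
#' @param n_volumes number of volumes (timepoints) in the scan.
#' @param tr_seconds repetition time in seconds.
#' @param spec a [window_spec()].
#' @return List with `starts_tr` (integer vector of 0-based start indices) and
#'   `width_tr` (integer window width in TRs).
#' @export
compute_window_starts <- function(n_volumes, tr_seconds,
                                  spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"), tr_seconds > 0, n_volumes >= 1)
  width_tr <- as.integer(round_half_up(spec$width_seconds / tr_seconds))
  if (n_volumes < width_tr)
    stop("series shorter than one window (", n_volumes, " < ", width_tr,
         " TR)")
  step_tr <- spec$step_seconds / tr_seconds
  n_win <- as.integer(floor((n_volumes - width_tr) / step_tr + 1e-9)) + 1L
  starts <- as.integer(round_half_up((seq_len(n_win) - 1L) * step_tr))
  stopifnot(all(starts + width_tr <= n_volumes), !is.unsorted(starts,
                                                              strictly = TRUE))
  list(starts_tr = starts, width_tr = width_tr)
}

#' Fisher z-transform of a correlation coefficient
#'
#' `z = atanh(r)`, variance-stabilizing the Pearson coefficient. Correlations
#' with `|r| >= 1 - 1e-7` are clipped to `sign(r) * atanh(1 - 1e-7)` so that
#' perfectly correlated in-window signals yield a large finite feature value
#' instead of infinity.
#'
#' @param r numeric vector of correlations in `[-1, 1]`.
#' @return Numeric vector of z-values.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) > 1))
    stop("correlations must be finite and within [-1, 1]")
  r_max <- 1 - 1e-7
  z <- numeric(length(r))
  clip <- abs(r) >= r_max
  z[clip] <- sign(r[clip]) * atanh(r_max)
  z[!clip] <- atanh(r[!clip])
  attributes(z) <- attributes(r)
  z
}

#' Connectivity matrix for one window
#'
#' Pearson correlation between every ROI pair over the window's rows, Fisher
#' z-transformed. The diagonal is `NA` by convention (self-correlation is
#' excluded from all downstream computation).
#'
#' @param ts an [roi_timeseries()].
#' @param start_tr 0-based window start index.
#' @param width_tr window width in TRs (>= 3).
#' @return Symmetric 10 x 10 matrix of z-values with `NA` diagonal.
#' @export
window_correlation <- function(ts, start_tr, width_tr) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (width_tr < 3L) stop("window must span at least 3 timepoints")
  if (start_tr < 0L || start_tr + width_tr > nrow(ts$data))
    stop("window [", start_tr, ", ", start_tr + width_tr,
         ") exceeds the series")
  slice <- ts$data[(start_tr + 1L):(start_tr + width_tr), , drop = FALSE]
  sds <- apply(slice, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant ROI ", paste(colnames(slice)[sds == 0], collapse = ", "),
         " within window starting at TR ", start_tr)
  z <- fisher_z(stats::cor(slice))
  diag(z) <- NA_real_
  z
}

#' Sliding-window connectivity for one scan
#'
#' Applies [compute_window_starts()] and [window_correlation()] over the scan,
#' yielding the ordered sequence of per-window Fisher-z connectivity matrices.
#'
#' @param ts an [roi_timeseries()].
#' @param spec a [window_spec()].
#' @return An object of class `windowed_fc`: list with `windows` (list of z
#'   matrices), `starts_tr`, `width_tr`, `subject_id`, `condition`.
#' @export
sliding_window_fc <- function(ts, spec = window_spec()) {
  w <- compute_window_starts(nrow(ts$data), ts$tr_seconds, spec)
  mats <- lapply(w$starts_tr, function(s)
    window_correlation(ts, s, w$width_tr))
  structure(list(windows = mats, starts_tr = w$starts_tr,
                 width_tr = w$width_tr, subject_id = ts$subject_id,
                 condition = ts$condition),
            class = "windowed_fc")
}

#' @export
print.windowed_fc <- function(x, ...) {
  cat(sprintf("Windowed FC: subject %s, %s, %d windows of %d TR\n",
              x$subject_id, x$condition, length(x$windows), x$width_tr))
  invisible(x)
}

#' Stack a windowed-FC object into a feature matrix
#'
#' @param wfc a `windowed_fc` from [sliding_window_fc()].
#' @return Numeric matrix, one row per window, 45 columns (upper-triangle
#'   z-features).
#' @export
fc_features <- function(wfc) {
  stopifnot(inherits(wfc, "windowed_fc"))
  t(vapply(wfc$windows, vectorize_upper_triangle,
           numeric(length(vectorize_upper_triangle(wfc$windows[[1L]])))))
}

#' Window all scans of a cohort into one pooled feature set
#'
#' Pools every scan's windowed features into a single matrix (the group
#' dataset that state clustering operates on) together with a window index
#' mapping each row back to its scan, subject and condition.
#'
#' @param cohort a `dfc_cohort`.
#' @param spec a [window_spec()].
#' @return List with `features` (n_windows x 45 matrix), `index` (data frame
#'   with scan_id, subject, condition, window), `windowed` (list of
#'   `windowed_fc`).
#' @export
cohort_windows <- function(cohort, spec = window_spec()) {
  stopifnot(inherits(cohort, "dfc_cohort"))
  wfcs <- lapply(cohort$scans, sliding_window_fc, spec = spec)
  feats <- lapply(wfcs, fc_features)
  idx <- do.call(rbind, lapply(names(wfcs), function(id) {
    n <- length(wfcs[[id]]$windows)
    data.frame(scan_id = id, subject = wfcs[[id]]$subject_id,
               condition = wfcs[[id]]$condition, window = seq_len(n))
  }))
  rownames(idx) <- NULL
  list(features = do.call(rbind, feats), index = idx, windowed = wfcs)
}
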