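#' ROI set spanning the dorsal attention, default mode and frontoparietal networks
#'
#' An `roi_set` fixes the ordered list of 10 region names and the network each
#' belongs to. All connectivity matrices, feature vectors and state blueprints in
#' the package are expressed in this order, so the set is validated strictly:
#' exactly 10 unique names, with 2 DAN, 4 DMN and 4 FPN members.
#'
#' @param roi_names character vector of 10 unique region identifiers, in the
#'   order columns appear in every matrix.
#' @param networks character vector of the same length with values in
#'   `"DAN"`, `"DMN"`, `"FPN"` giving each region's network.
#' @return An object of class `roi_set` with elements `roi_names` (character)
#'   and `network_of` (named character, region -> network).
#' @seealso [default_roi_set()]
#' @export
roi_set <- function(roi_names, networks) {
  roi_names <- as.character(roi_names)
  networks <- as.character(networks)
  if (length(roi_names) != 10L)
    stop("an roi_set must contain exactly 10 ROIs, got ", length(roi_names))
  if (anyDuplicated(roi_names))
    stop("ROI names must be unique")
  if (length(networks) != length(roi_names))
    stop("'networks' must have one entry per ROI")
  if (!all(networks %in% c("DAN", "DMN", "FPN")))
    stop("networks must be one of DAN, DMN, FPN")
  sizes <- table(factor(networks, levels = c("DAN", "DMN", "FPN")))
  if (!(sizes[["DAN"]] == 2L && sizes[["DMN"]] == 4L && sizes[["FPN"]] == 4L))
    stop("network sizes must be DAN = 2, DMN = 4, FPN = 4; got ",
         paste(names(sizes), sizes, sep = "=", collapse = ", "))
  structure(list(roi_names = roi_names,
                 network_of = stats::setNames(networks, roi_names)),
            class = "roi_set")
}

#' Default 10-ROI parcellation
#'
#' The default set: bilateral intraparietal sulcus (DAN); medial prefrontal
#' cortex, posterior cingulate cortex and bilateral lateral parietal cortex
#' (DMN); bilateral lateral prefrontal cortex and bilateral posterior parietal
#' cortex (FPN).
#'
#' @return An [roi_set()].
#' @export
default_roi_set <- function() {
  roi_set(
    roi_names = c("IPSl", "IPSr",
                  "MPFC", "PCC", "LPl", "LPr",
                  "LPFCl", "LPFCr", "pPCl", "pPCr"),
    networks = c("DAN", "DAN",
                 "DMN", "DMN", "DMN", "DMN",
                 "FPN", "FPN", "FPN", "FPN")
  )
}

#' @export
print.roi_set <- function(x, ...) {
  cat("ROI set (10 regions):\n")
  for (net in c("DAN", "DMN", "FPN"))
    cat(sprintf("  %s: %s\n", net,
                paste(names(x$network_of)[x$network_of == net], collapse = ", ")))
  invisible(x)
}

#' Single-scan ROI time-series container
#'
#' Bundles one scan's T x 10 signal matrix with its acquisition metadata. The
#' columns are reordered to the `roi_set` order on construction; constant or
#' non-finite columns are rejected because windowed correlation is undefined on
#' them.
#'
#' @param data numeric matrix or data frame, rows = timepoints, columns named
#'   by ROI.
#' @param subject_id scan's subject identifier.
#' @param condition one of `"pre_rest"`, `"task"`, `"post_rest"`.
#' @param tr_seconds repetition time in seconds (volume-to-volume interval).
#' @param roi_set the [roi_set()] naming the expected columns.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, subject_id, condition, tr_seconds,
                           roi_set = default_roi_set()) {
  condition <- match.arg(condition, c("pre_rest", "task", "post_rest"))
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("tr_seconds must be a positive scalar")
  data <- as.matrix(data)
  missing_cols <- setdiff(roi_set$roi_names, colnames(data))
  if (length(missing_cols))
    stop("missing ROI column(s): ", paste(missing_cols, collapse = ", "))
  data <- data[, roi_set$roi_names, drop = FALSE]
  if (!is.numeric(data))
    stop("non-numeric values in ROI time series")
  if (any(!is.finite(data)))
    stop("non-finite values in ROI time series")
  if (nrow(data) < 2L)
    stop("a time series needs at least 2 timepoints")
  sds <- apply(data, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant ROI column(s): ",
         paste(colnames(data)[sds == 0], collapse = ", "))
  structure(list(data = data, subject_id = as.character(subject_id),
                 condition = condition, tr_seconds = tr_seconds,
                 roi_set = roi_set),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("ROI time series: subject %s, %s, %d volumes @ TR %.3g s, %d ROIs\n",
              x$subject_id, x$condition, nrow(x$data), x$tr_seconds,
              ncol(x$data)))
  invisible(x)
}

#' Read one scan's ROI time series from tab-separated text
#'
#' Expects a header row of ROI names and one row per timepoint. Metadata
#' (subject, condition, TR) is not stored in the file; it is supplied by the
#' caller, typically from a cohort manifest.
#'
#' @inheritParams roi_timeseries
#' @param path path to a TSV file.
#' @return An [roi_timeseries()].
#' @export
read_roi_timeseries <- function(path, subject_id, condition, tr_seconds,
                                roi_set = default_roi_set()) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  m <- suppressWarnings(vapply(tab, as.numeric, numeric(nrow(tab))))
  if (any(is.na(m) & !is.na(as.matrix(tab))))
    stop("non-numeric cell(s) in ", path)
  colnames(m) <- colnames(tab)
  roi_timeseries(m, subject_id = subject_id, condition = condition,
                 tr_seconds = tr_seconds, roi_set = roi_set)
}

#' Write one scan's ROI time series as tab-separated text
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces the doubles exactly.
#'
#' @param ts an [roi_timeseries()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_roi_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  chr <- matrix(sprintf("%.17g", ts$data), nrow = nrow(ts$data))
  lines <- c(paste(colnames(ts$data), collapse = "\t"),
             apply(chr, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a cohort to a directory of TSV scans plus a JSON manifest
#'
#' The manifest records subject, condition, TR, volume count and the relative
#' path of each scan file; it is the single source of metadata when reading the
#' cohort back.
#'
#' @param cohort a `dfc_cohort` (see [simulate_cohort()]).
#' @param dir output directory, created if needed.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dfc_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  man$path <- sprintf("%s.tsv", man$scan_id)
  for (i in seq_len(nrow(man)))
    write_roi_timeseries(cohort$scans[[man$scan_id[i]]],
                         file.path(dir, man$path[i]))
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, manifest_path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest_path)
}

#' Read a cohort from a manifest written by [write_cohort()]
#'
#' @param manifest_path path to `manifest.json`.
#' @param roi_set expected [roi_set()].
#' @return A `dfc_cohort` (without ground truth).
#' @export
read_cohort <- function(manifest_path, roi_set = default_roi_set()) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  scans <- lapply(seq_len(nrow(man)), function(i)
    read_roi_timeseries(file.path(dir, man$path[i]),
                        subject_id = man$subject[i],
                        condition = man$condition[i],
                        tr_seconds = man$tr_seconds[i],
                        roi_set = roi_set))
  names(scans) <- man$scan_id
  structure(list(scans = scans,
                 manifest = man[, c("scan_id", "subject", "condition",
                                    "tr_seconds", "n_volumes")],
                 truth = NULL),
            class = "dfc_cohort")
}

#' @export
print.dfc_cohort <- function(x, ...) {
  tab <- table(x$manifest$condition)
  cat(sprintf("DFC cohort: %d scans, %d subjects (%s)\n",
              nrow(x$manifest), length(unique(x$manifest$subject)),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  if (!is.null(x$truth)) cat("  planted ground truth attached\n")
  invisible(x)
}
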