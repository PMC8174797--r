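#' K-means estimation of connectivity states
#'
#' Clusters windowed connectivity feature vectors with k-means (Euclidean
#' distance, Lloyd iterations) over `n_init` random restarts, keeping the
#' lowest-inertia solution. Restarts whose initialization leads to an empty or
#' duplicate-center failure are re-initialized. After the best restart is
#' chosen, every window is assigned to its nearest centroid and states are
#' renumbered 1..k by decreasing mean absolute off-diagonal centroid z, so the
#' lowest-connectivity state always receives the highest label and labels are
#' reproducible across seeds.
#'
#' Features are clustered on raw z-values without per-feature standardization:
#' all 45 features share the Fisher-z scale.
#'
#' @param features numeric matrix, one row per window.
#' @param k number of states.
#' @param seed RNG seed controlling all restarts (results are a deterministic
#'   function of it).
#' @param n_init number of random restarts (default 25; set to 1 for a single
#'   literal k-means run).
#' @param max_iter Lloyd iterations per restart (default 25).
#' @return An object of class `state_solution`: `k`, `centroids` (k x p
#'   matrix), `assignments` (integer vector), `inertia`, `sizes`, `seed`,
#'   `n_init`, `max_iter`.
#' @export
kmeans_states <- function(features, k, seed = 20210528L, n_init = 25L,
                          max_iter = 25L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n <= k) stop("need more points (", n, ") than clusters (", k, ")")
  best <- NULL
  withr::with_seed(seed, {
    for (i in seq_len(n_init)) {
      fit <- NULL
      for (attempt in seq_len(20L)) {
        init <- features[sample.int(n, k), , drop = FALSE]
        fit <- tryCatch(
          suppressWarnings(stats::kmeans(features, centers = init,
                                         iter.max = max_iter,
                                         algorithm = "Lloyd")),
          error = function(e) NULL)
        if (!is.null(fit) && all(fit$size > 0L)) break
        fit <- NULL
      }
      if (is.null(fit))
        stop("k-means failed to find ", k, " non-empty clusters")
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  centers <- best$centers
  ord <- order(-rowMeans(abs(centers)))
  centers <- centers[ord, , drop = FALSE]
  rownames(centers) <- paste0("state", seq_len(k))
  assignments <- assign_windows(centers, features)
  if (length(unique(assignments)) < k)
    stop("a state lost all windows at the final assignment")
  inertia <- sum((features - centers[assignments, , drop = FALSE])^2)
  structure(list(k = as.integer(k), centroids = centers,
                 assignments = assignments, inertia = inertia,
                 sizes = tabulate(assignments, k), seed = seed,
                 n_init = as.integer(n_init),
                 max_iter = as.integer(max_iter)),
            class = "state_solution")
}

#' @export
print.state_solution <- function(x, ...) {
  cat(sprintf("State solution: k = %d, %d windows, inertia %.4g\n",
              x$k, length(x$assignments), x$inertia))
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Centroids of a state solution as connectivity matrices
#'
#' @param solution a `state_solution`.
#' @param roi_names optional ROI names for dimnames.
#' @return List of k symmetric z-matrices with `NA` diagonal.
#' @export
state_centroid_matrices <- function(solution, roi_names = NULL) {
  stopifnot(inherits(solution, "state_solution"))
  lapply(seq_len(solution$k), function(s)
    devectorize_upper_triangle(solution$centroids[s, ], roi_names))
}

#' Assign windows to their nearest state centroid
#'
#' Euclidean nearest-centroid classification; distance ties are broken in
#' favour of the lowest state label.
#'
#' @param centroids k x p centroid matrix, or a `state_solution`.
#' @param features numeric matrix of window features (n x p).
#' @return Integer vector of state labels in 1..k.
#' @export
assign_windows <- function(centroids, features) {
  if (inherits(centroids, "state_solution")) centroids <- centroids$centroids
  centroids <- as.matrix(centroids)
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  features <- as.matrix(features)
  if (ncol(features) != ncol(centroids))
    stop("feature dimensionality (", ncol(features),
         ") does not match centroids (", ncol(centroids), ")")
  d2 <- outer(rowSums(features^2), rowSums(centroids^2), "+") -
    2 * features %*% t(centroids)
  unname(max.col(-d2, ties.method = "first"))
}
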