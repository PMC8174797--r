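#' Vectorize the upper triangle of a connectivity matrix
#'
#' Connectivity matrices are symmetric with an undefined diagonal
#' (self-correlation carries no information and its Fisher z is infinite), so
#' each matrix is represented for clustering by its 45 upper-triangular
#' entries. The ordering is fixed: pairs (i, j) with i < j in row-major order,
#' i.e. (1,2), (1,3), ..., (1,10), (2,3), ... This ordering is what makes
#' centroids comparable across runs and solutions.
#'
#' @param m symmetric numeric matrix; the diagonal may be `NA` and is ignored.
#' @param tol symmetry tolerance.
#' @return Numeric vector of length n(n-1)/2, named `"roi_i~roi_j"` when `m`
#'   has dimnames.
#' @seealso [devectorize_upper_triangle()]
#' @export
vectorize_upper_triangle <- function(m, tol = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  off <- abs(m - t(m))
  diag(off) <- 0
  if (any(off > tol, na.rm = TRUE) || any(is.na(m[lower.tri(m)])))
    stop("matrix is not symmetric")
  # lower.tri in column-major order enumerates exactly the i<j pairs row-major
  v <- m[lower.tri(m)]
  if (!is.null(rownames(m))) {
    idx <- which(lower.tri(m), arr.ind = TRUE)
    names(v) <- paste(rownames(m)[idx[, 2L]], rownames(m)[idx[, 1L]],
                      sep = "~")
  }
  v
}

#' Rebuild a symmetric matrix from its upper-triangle vector
#'
#' Inverse of [vectorize_upper_triangle()]; the diagonal is set to `NA`
#' (undefined by convention).
#'
#' @param v numeric vector of length n(n-1)/2.
#' @param roi_names optional dimnames for the result.
#' @return Symmetric n x n matrix with `NA` diagonal.
#' @export
devectorize_upper_triangle <- function(v, roi_names = NULL) {
  p <- length(v)
  n <- (1 + sqrt(1 + 8 * p)) / 2
  if (n != round(n))
    stop("length ", p, " is not a triangular number")
  n <- as.integer(round(n))
  m <- matrix(NA_real_, n, n)
  m[lower.tri(m)] <- v
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  if (!is.null(roi_names)) dimnames(m) <- list(roi_names, roi_names)
  m
}
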