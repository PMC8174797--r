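# Optimal one-to-one matching of state centroids between two solutions.

# Minimum-cost linear assignment by shortest augmenting paths
# (Jonker-Volgenant / Hungarian with potentials), O(n^3). Returns, for each
# row, the column assigned to it.
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  u <- numeric(n)            # row potentials
  v <- numeric(n + 1L)       # column potentials (n+1 = virtual source column)
  p <- integer(n + 1L)       # p[j]: row currently assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0L) ans[p[j]] <- j
  ans
}

#' Match states between two solutions by centroid correlation
#'
#' Computes the k x k matrix of Pearson correlations between the centroid
#' z-vectors of two equal-k state solutions and finds the one-to-one pairing
#' that maximizes the total correlation (optimal linear assignment). Each
#' matched pair is then tested with a Pearson correlation test over the 45
#' z-features, reporting r, a two-sided p-value and a confidence interval —
#' the comparison used to quantify convergence between solutions obtained
#' from, e.g., individual versus group-atlas parcellations.
#'
#' @param A,B `state_solution` objects with equal `k`, or bare k x p centroid
#'   matrices.
#' @param ci_level confidence level for the per-pair interval.
#' @return An object of class `state_matching`: `permutation` (state i of A is
#'   paired with `permutation[i]` of B), `r`, `p`, `ci` (k x 2), `total_r`,
#'   `r_matrix`.
#' @export
match_states <- function(A, B, ci_level = 0.95) {
  ca <- if (inherits(A, "state_solution")) A$centroids else as.matrix(A)
  cb <- if (inherits(B, "state_solution")) B$centroids else as.matrix(B)
  if (nrow(ca) != nrow(cb))
    stop("solutions have different numbers of states (", nrow(ca), " vs ",
         nrow(cb), ")")
  if (ncol(ca) != ncol(cb))
    stop("centroid dimensionality differs")
  k <- nrow(ca)
  r_mat <- stats::cor(t(ca), t(cb))
  perm <- solve_assignment(-r_mat)
  tests <- lapply(seq_len(k), function(i)
    stats::cor.test(ca[i, ], cb[perm[i], ], conf.level = ci_level))
  ci <- t(vapply(tests, function(tt) as.numeric(tt$conf.int), numeric(2L)))
  colnames(ci) <- c("lower", "upper")
  structure(list(permutation = stats::setNames(perm, rownames(ca)),
                 r = vapply(tests, function(tt) unname(tt$estimate),
                            numeric(1L)),
                 p = vapply(tests, function(tt) tt$p.value, numeric(1L)),
                 ci = ci,
                 total_r = sum(r_mat[cbind(seq_len(k), perm)]),
                 r_matrix = r_mat,
                 ci_level = ci_level),
            class = "state_matching")
}

#' @export
print.state_matching <- function(x, ...) {
  k <- length(x$permutation)
  cat(sprintf("State matching (k = %d), total r = %.3f\n", k, x$total_r))
  for (i in seq_len(k))
    cat(sprintf("  %s -> %d: r = %.3f, p = %.3g, %d%% CI [%.3f, %.3f]\n",
                names(x$permutation)[i], x$permutation[i], x$r[i], x$p[i],
                round(100 * x$ci_level), x$ci[i, 1L], x$ci[i, 2L]))
  invisible(x)
}
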