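# Cluster-validity indices and the majority rule for choosing the number of
# connectivity states. Each index examines the k-means solutions over the
# candidate range and nominates one k; the k with the most nominations wins,
# ties going to the smallest k.
#
# Level indices (silhouette, CH, DB, point-biserial) nominate the best level;
# hierarchy indices (KL, Hartigan, Ball-Hall, Scott-Symons, Friedman, Rubin)
# nominate where the criterion curve changes fastest (first or second
# differences), so solutions one k beyond the candidate range are also fitted.

total_ss <- function(x) sum(sweep(x, 2L, colMeans(x))^2)

# pooled within-cluster scatter matrix
scatter_within <- function(x, labels, k) {
  W <- matrix(0, ncol(x), ncol(x))
  for (c_ in seq_len(k)) {
    xc <- x[labels == c_, , drop = FALSE]
    xc <- sweep(xc, 2L, colMeans(xc))
    W <- W + crossprod(xc)
  }
  W
}

index_ch <- function(wss_k, tss, n, k) {
  ((tss - wss_k) / (k - 1)) / (wss_k / (n - k))
}

index_db <- function(x, labels, centers) {
  k <- nrow(centers)
  s <- vapply(seq_len(k), function(c_) {
    pts <- x[labels == c_, , drop = FALSE]
    sqrt(mean(rowSums(sweep(pts, 2L, centers[c_, ])^2)))
  }, numeric(1L))
  dcent <- as.matrix(stats::dist(centers))
  mean(vapply(seq_len(k), function(i)
    max(vapply(setdiff(seq_len(k), i), function(j)
      (s[i] + s[j]) / dcent[i, j], numeric(1L))), numeric(1L)))
}

index_silhouette <- function(dist_obj, labels) {
  mean(cluster::silhouette(labels, dist = dist_obj)[, "sil_width"])
}

# point-biserial: correlation between pairwise distance and the
# different-cluster indicator
index_ptbiserial <- function(dist_vec, labels) {
  stats::cor(dist_vec, as.numeric(as.vector(stats::dist(labels)) != 0))
}

#' Majority-rule selection of the number of states
#'
#' Runs k-means over a range of candidate cluster counts, scores each
#' solution with a panel of cluster-validity indices, and selects the k
#' nominated by the most indices (majority rule); ties are broken in favour
#' of the smallest k. The default panel:
#'
#' * `silhouette` — maximal mean silhouette width (`cluster::silhouette`);
#' * `ch` — maximal Calinski-Harabasz pseudo-F;
#' * `db` — minimal Davies-Bouldin index;
#' * `ptbiserial` — maximal point-biserial correlation between pairwise
#'   distances and cluster co-membership;
#' * `kl` — maximal Krzanowski-Lai index
#'   `|DIFF(k)/DIFF(k+1)|`, `DIFF(k) = (k-1)^(2/p) W(k-1) - k^(2/p) W(k)`,
#'   the standard formalization of the within-SS elbow;
#' * `hartigan` — maximal drop of Hartigan's statistic
#'   `(W(k)/W(k+1) - 1)(n - k - 1)`;
#' * `ball_hall` — maximal drop of the mean within-cluster dispersion
#'   `W(k)/k`;
#' * `scott` — maximal increase of Scott-Symons' `n log(|T|/|W(k)|)`;
#' * `friedman` — maximal increase of Friedman-Rubin's `trace(W(k)^{-1} B(k))`;
#' * `rubin` — extremal second difference of `log(|T|/|W(k)|)`
#'   (determinant-ratio curvature).
#'
#' Here `W` is the (pooled within-cluster) scatter, `B` the between scatter
#' and `T` the total scatter. Level indices answer "where is the score best";
#' difference-based indices answer "where does adding a cluster stop paying",
#' which is what locates the kink of a criterion curve when clusters overlap.
#' The gap statistic and the Dunn index are deliberately not in the default
#' panel: with thousands of windows the gap's simulation standard error
#' vanishes, degenerating its one-SE stopping rule to the largest candidate,
#' and Dunn's single-linkage minimum separation between overlapping clusters
#' is noise-dominated.
#'
#' @param features numeric matrix of window features.
#' @param k_range candidate numbers of clusters (default 2:8, contiguous).
#' @param index_set subset of the panel to use (>= 1 names above).
#' @param seed RNG seed for the k-means restarts.
#' @param n_init k-means restarts per candidate k.
#' @param max_iter Lloyd iterations.
#' @return An object of class `k_selection`: `chosen_k`, `votes` (named
#'   integer), `per_index_choice`, `k_range`, `wss`.
#' @export
select_k_majority <- function(features,
                              k_range = 2:8,
                              index_set = c("silhouette", "ch", "db",
                                            "ptbiserial", "kl", "hartigan",
                                            "ball_hall", "scott", "friedman",
                                            "rubin"),
                              seed = 20210528L, n_init = 10L,
                              max_iter = 25L) {
  index_set <- match.arg(index_set, several.ok = TRUE)
  features <- as.matrix(features)
  k_range <- sort(unique(as.integer(k_range)))
  if (!all(diff(k_range) == 1L))
    stop("k_range must be contiguous (difference indices need neighbours)")
  n <- nrow(features)
  if (n <= max(k_range) + 1L)
    stop("need more points (", n, ") than the largest candidate k (",
         max(k_range), ") plus one")
  ks <- k_range
  # solutions over k_range plus neighbours needed by difference indices
  k_all <- sort(unique(c(if (min(ks) > 2L) min(ks) - 1L, ks,
                         max(ks) + 1L, max(ks) + 2L)))
  sub <- derive_seeds(seed, length(k_all))
  sols <- lapply(seq_along(k_all), function(i)
    kmeans_states(features, k_all[i], seed = sub[i], n_init = n_init,
                  max_iter = max_iter))
  tss <- total_ss(features)
  # wss indexed by cluster count; wss[1] = TSS (the one-cluster solution)
  wss <- numeric(max(k_all))
  wss[1L] <- tss
  for (i in seq_along(k_all)) wss[k_all[i]] <- sols[[i]]$inertia
  p <- ncol(features)

  need_det <- any(c("scott", "friedman", "rubin") %in% index_set)
  if (need_det) {
    xt <- sweep(features, 2L, colMeans(features))
    Tm <- crossprod(xt)
    ld <- numeric(max(k_all))          # log|W(k)|; k = 1 is total scatter
    trwb <- numeric(max(k_all))        # trace(W^-1 B)
    ld[1L] <- as.numeric(determinant(Tm)$modulus)
    for (i in seq_along(k_all)) {
      W <- scatter_within(features, sols[[i]]$assignments, k_all[i])
      ld[k_all[i]] <- as.numeric(determinant(W)$modulus)
      trwb[k_all[i]] <- sum(diag(solve(W, Tm - W)))
    }
  }
  need_dist <- any(c("silhouette", "ptbiserial") %in% index_set)
  if (need_dist) {
    dist_obj <- stats::dist(features)
    dist_vec <- if ("ptbiserial" %in% index_set) as.vector(dist_obj) else NULL
  }
  sol_at <- function(k) sols[[match(k, k_all)]]

  choice <- integer(0)
  if ("silhouette" %in% index_set) {
    v <- vapply(ks, function(k)
      index_silhouette(dist_obj, sol_at(k)$assignments), numeric(1L))
    choice["silhouette"] <- ks[which.max(v)]
  }
  if ("ch" %in% index_set) {
    v <- vapply(ks, function(k) index_ch(wss[k], tss, n, k), numeric(1L))
    choice["ch"] <- ks[which.max(v)]
  }
  if ("db" %in% index_set) {
    v <- vapply(ks, function(k)
      index_db(features, sol_at(k)$assignments, sol_at(k)$centroids),
      numeric(1L))
    choice["db"] <- ks[which.min(v)]
  }
  if ("ptbiserial" %in% index_set) {
    v <- vapply(ks, function(k)
      index_ptbiserial(dist_vec, sol_at(k)$assignments), numeric(1L))
    choice["ptbiserial"] <- ks[which.max(v)]
  }
  if ("kl" %in% index_set) {
    diffk <- function(k) (k - 1)^(2 / p) * wss[k - 1L] - k^(2 / p) * wss[k]
    v <- vapply(ks, function(k) abs(diffk(k) / diffk(k + 1L)), numeric(1L))
    choice["kl"] <- ks[which.max(v)]
  }
  if ("hartigan" %in% index_set) {
    H <- function(k) (wss[k] / wss[k + 1L] - 1) * (n - k - 1)
    v <- vapply(ks, function(k) H(k - 1L) - H(k), numeric(1L))
    choice["hartigan"] <- ks[which.max(v)]
  }
  if ("ball_hall" %in% index_set) {
    v <- vapply(ks, function(k)
      wss[k - 1L] / (k - 1) - wss[k] / k, numeric(1L))
    choice["ball_hall"] <- ks[which.max(v)]
  }
  if ("scott" %in% index_set) {
    v <- vapply(ks, function(k)
      n * (ld[1L] - ld[k]) - n * (ld[1L] - ld[k - 1L]), numeric(1L))
    choice["scott"] <- ks[which.max(v)]
  }
  if ("friedman" %in% index_set) {
    v <- vapply(ks, function(k)
      trwb[k] - (if (k == 2L) 0 else trwb[k - 1L]), numeric(1L))
    choice["friedman"] <- ks[which.max(v)]
  }
  if ("rubin" %in% index_set) {
    R <- function(k) ld[1L] - ld[k]  # log(|T|/|W(k)|)
    v <- vapply(ks, function(k)
      R(k - 1L) - 2 * R(k) + R(k + 1L), numeric(1L))
    choice["rubin"] <- ks[which.min(v)]
  }

  votes <- table(factor(choice, levels = ks))
  chosen <- ks[which.max(votes)]  # which.max takes the first (smallest k)
  structure(list(chosen_k = chosen,
                 votes = stats::setNames(as.integer(votes), names(votes)),
                 per_index_choice = choice,
                 k_range = ks,
                 wss = stats::setNames(wss[ks], ks)),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("Majority-rule k selection: chosen k = %d\n", x$chosen_k))
  nz <- x$votes[x$votes > 0]
  cat("  votes:", paste(names(nz), nz, sep = " -> ", collapse = ", "), "\n")
  cat("  per index:",
      paste(names(x$per_index_choice), x$per_index_choice, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}
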