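# Shared fixtures and brute-force oracles used across test files.

# A small, fast cohort: 4 subjects, shortened scans, full grid.
small_cohort <- function(seed = 42, n_subjects = 4) {
  design <- cohort_design(
    n_subjects = n_subjects,
    conditions = list(pre_rest = c(120, 2.0), task = c(150, 1.5)),
    missing_cells = data.frame(subject = character(),
                               condition = character()),
    seed = seed)
  simulate_cohort(design)
}

random_symmetric <- function(n = 10, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * n), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- NA_real_
    m
  })
}

# Per-window majority vote of the planted per-TR state sequence: the ground
# truth a window label is compared against.
planted_window_labels <- function(cohort, spec = window_spec()) {
  lapply(seq_len(nrow(cohort$manifest)), function(i) {
    tr_states <- cohort$truth[[i]]$states
    w <- compute_window_starts(cohort$manifest$n_volumes[i],
                               cohort$manifest$tr_seconds[i], spec)
    vapply(w$starts_tr, function(s0) {
      seg <- tr_states[(s0 + 1):(s0 + w$width_tr)]
      as.integer(names(which.max(table(seg))))
    }, integer(1))
  })
}

# Brute-force best assignment (maximum total score) over all permutations.
brute_force_assignment <- function(score) {
  k <- nrow(score)
  perms <- all_permutations(k)
  totals <- vapply(perms, function(p) sum(score[cbind(seq_len(k), p)]),
                   numeric(1))
  list(permutation = perms[[which.max(totals)]], total = max(totals))
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1L))
    for (pos in 0:(k - 1L))
      out[[length(out) + 1L]] <- as.integer(append(p, k, after = pos))
  out
}
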