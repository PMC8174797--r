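#' Fractional occupancy of states per scan
#'
#' For each scan, the number of windows classified to a state divided by the
#' scan's total number of windows — the proportion of time spent in that
#' state. States absent from a scan get proportion 0, so every
#' (subject, condition) has a complete, sum-to-one set of rows.
#'
#' @param labels list of per-scan integer label sequences (one element per
#'   manifest row, in order).
#' @param manifest data frame with one row per scan, containing at least
#'   `subject` and `condition`.
#' @param k number of states; defaults to the maximum observed label.
#' @return A data frame of class `occupancy_table` with columns `subject`,
#'   `condition`, `state` (factor), `proportion`, `n_windows`.
#' @export
occupancy_table <- function(labels, manifest, k = NULL) {
  if (!is.list(labels)) labels <- list(labels)
  if (length(labels) != nrow(manifest))
    stop("labels (", length(labels), " scans) do not match the manifest (",
         nrow(manifest), " rows)")
  if (is.null(k)) k <- max(unlist(labels))
  out <- do.call(rbind, lapply(seq_along(labels), function(i) {
    lab <- labels[[i]]
    if (any(lab < 1L | lab > k))
      stop("scan ", i, " has labels outside 1..", k)
    n <- length(lab)
    data.frame(subject = manifest$subject[i],
               condition = manifest$condition[i],
               state = factor(seq_len(k), levels = seq_len(k)),
               proportion = tabulate(lab, k) / n,
               n_windows = n)
  }))
  rownames(out) <- NULL
  class(out) <- c("occupancy_table", "data.frame")
  attr(out, "k") <- as.integer(k)
  out
}

#' Per-scan state-transition counts and dwell runs
#'
#' Counts consecutive-window label pairs (including self-transitions) and
#' records dwell runs — maximal stretches of constant label.
#'
#' @param labels integer label sequence for one scan (length >= 2).
#' @param k number of states.
#' @return List with `counts` (k x k matrix, `counts[i, j]` = transitions
#'   i -> j), `dwell` (data frame of run `state` and `length`), `n_transitions`.
#' @export
transition_counts <- function(labels, k = max(labels)) {
  n <- length(labels)
  if (n < 2L) stop("need at least 2 windows to count transitions")
  counts <- matrix(0L, k, k,
                   dimnames = list(from = seq_len(k), to = seq_len(k)))
  from <- labels[-n]
  to <- labels[-1L]
  for (i in seq_len(n - 1L))
    counts[from[i], to[i]] <- counts[from[i], to[i]] + 1L
  runs <- rle(labels)
  list(counts = counts,
       dwell = data.frame(state = runs$values, length = runs$lengths),
       n_transitions = n - 1L)
}

#' Mixed-effects test of condition-by-state occupancy differences
#'
#' Fits a linear mixed model to the fractional-occupancy table with the
#' condition-by-state interaction as fixed effects and a random intercept per
#' subject (`nlme::lme`, REML), tolerating unbalanced designs with missing
#' subject-condition cells. The interaction is tested with the model ANOVA
#' (containment denominator degrees of freedom). Post hoc
#' estimated-marginal-mean contrasts between conditions within each state are
#' computed with `emmeans`, Bonferroni-adjusted by an explicit `family_size`
#' (default 5, one contrast family per state), and accompanied by a Cohen's d
#' (EMM difference divided by the model residual SD) and a confidence
#' interval.
#'
#' @param table an [occupancy_table()].
#' @param family_size Bonferroni multiplier for the contrast p-values.
#' @param ci_level confidence level for contrast intervals.
#' @param contrasts if `FALSE`, skip the post hoc contrasts (faster; e.g. in
#'   simulation loops that only use the interaction test).
#' @return An object of class `occupancy_lme`: `interaction` (list with `F`,
#'   `df_num`, `df_den`, `p`), `contrasts` (data frame), `sigma`,
#'   `family_size`, `anova`, `model`.
#' @export
fit_occupancy_lme <- function(table, family_size = 5L, ci_level = 0.95,
                              contrasts = TRUE) {
  d <- as.data.frame(table)
  req <- c("subject", "condition", "state", "proportion")
  if (!all(req %in% names(d)))
    stop("occupancy table must have columns ",
         paste(req, collapse = ", "))
  d$condition <- factor(d$condition,
                        levels = intersect(c("pre_rest", "task", "post_rest",
                                             "rest"),
                                           unique(as.character(d$condition))))
  if (any(is.na(d$condition)))
    d$condition <- factor(as.character(table$condition))
  d$state <- factor(d$state)
  d$subject <- factor(d$subject)
  if (nlevels(d$condition) < 2L || nlevels(d$state) < 2L)
    stop("need at least 2 conditions and 2 states")
  n_subj <- tapply(d$subject, d$condition,
                   function(s) length(unique(s)))
  if (any(n_subj < 2L))
    stop("condition ", names(n_subj)[which(n_subj < 2L)[1L]],
         " has fewer than 2 subjects")
  cells <- table(d$condition, d$state)
  if (any(cells == 0L)) {
    bad <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    stop("design is rank deficient: no data in cell condition=",
         rownames(cells)[bad[1L]], ", state=", colnames(cells)[bad[2L]])
  }
  fit <- nlme::lme(proportion ~ condition * state, random = ~ 1 | subject,
                   data = d, method = "REML",
                   control = nlme::lmeControl(returnObject = TRUE))
  av <- stats::anova(fit)
  row <- grep("condition:state", rownames(av))
  interaction <- list(F = av[row, "F-value"],
                      df_num = av[row, "numDF"],
                      df_den = av[row, "denDF"],
                      p = av[row, "p-value"])
  contr_df <- NULL
  if (contrasts) {
    emm <- emmeans::emmeans(fit, ~ condition | state, data = d)
    prs <- emmeans::contrast(emm, method = "pairwise", adjust = "none")
    ps <- summary(prs)
    cis <- stats::confint(prs, level = ci_level)
    contr_df <- data.frame(
      state = ps$state,
      contrast = as.character(ps$contrast),
      estimate = ps$estimate,
      se = ps$SE,
      df = ps$df,
      t = ps$t.ratio,
      p_raw = ps$p.value,
      p_adj = pmin(1, ps$p.value * family_size),
      cohen_d = ps$estimate / stats::sigma(fit),
      lower = cis$lower.CL,
      upper = cis$upper.CL)
  }
  structure(list(interaction = interaction, contrasts = contr_df,
                 sigma = stats::sigma(fit), family_size = family_size,
                 ci_level = ci_level, anova = av, model = fit),
            class = "occupancy_lme")
}

#' @export
print.occupancy_lme <- function(x, digits = 4, ...) {
  it <- x$interaction
  cat(sprintf("Condition x state interaction: F(%d, %d) = %.4f, p = %.4g\n",
              it$df_num, it$df_den, it$F, it$p))
  if (!is.null(x$contrasts)) {
    cat(sprintf("Post hoc EMM contrasts (Bonferroni family = %d):\n",
                x$family_size))
    print(format(x$contrasts, digits = digits), row.names = FALSE)
  }
  invisible(x)
}

#' Correlation between behavioural responses and state occupancy
#'
#' Pearson correlation, per state, between a per-subject response count and
#' the proportion of time spent in the state during one condition.
#'
#' @param responses named numeric vector of per-subject response counts.
#' @param table an [occupancy_table()].
#' @param condition condition whose occupancies are used.
#' @return Data frame with columns `state`, `n`, `r`, `p`.
#' @export
response_occupancy_correlation <- function(responses, table,
                                           condition = "task") {
  d <- as.data.frame(table)
  d <- d[d$condition == condition, ]
  if (!nrow(d)) stop("no rows for condition ", condition)
  subjects <- intersect(names(responses), unique(as.character(d$subject)))
  if (length(subjects) < 3L)
    stop("need at least 3 subjects with both measures")
  if (stats::sd(responses[subjects]) == 0)
    stop("responses are constant; correlation undefined")
  states <- sort(unique(d$state))
  out <- do.call(rbind, lapply(states, function(s) {
    ds <- d[d$state == s, ]
    prop <- stats::setNames(ds$proportion, as.character(ds$subject))[subjects]
    tt <- stats::cor.test(responses[subjects], prop)
    data.frame(state = s, n = length(subjects),
               r = unname(tt$estimate), p = tt$p.value)
  }))
  rownames(out) <- NULL
  out
}
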