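# Occupancy tables shaped like the study design (15 subjects, 3 conditions
# with one missing post-task cell, 5 states) for mixed-model structure tests.
study_manifest <- function() {
  man <- expand.grid(subject = sprintf("S%02d", 1:15),
                     condition = c("pre_rest", "task", "post_rest"),
                     stringsAsFactors = FALSE)
  man[!(man$subject == "S15" & man$condition == "post_rest"), ]
}

study_occupancy <- function(seed, profiles = NULL) {
  man <- study_manifest()
  nw <- c(pre_rest = 39L, task = 79L, post_rest = 39L)
  if (is.null(profiles))
    profiles <- matrix(0.2, 3, 5, dimnames = list(names(nw), NULL))
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max,
                                             nrow(man)))
  labels <- lapply(seq_len(nrow(man)), function(i)
    simulate_window_labels(nw[[man$condition[i]]],
                           profiles[man$condition[i], ], seed = seeds[i]))
  occupancy_table(labels, man, k = 5)
}

test_that("the interaction test has the study's degrees-of-freedom structure", {
  occ <- study_occupancy(1)
  fit <- fit_occupancy_lme(occ)
  expect_equal(fit$interaction$df_num, 8)
  # containment df: 220 rows - 15 subjects - 14 non-intercept fixed effects
  expect_equal(fit$interaction$df_den, 191)
  expect_equal(nrow(fit$contrasts), 15)  # 3 condition pairs x 5 states
  expect_equal(fit$contrasts$p_adj,
               pmin(1, fit$contrasts$p_raw * 5), tolerance = 1e-12)
  expect_equal(fit$contrasts$cohen_d,
               fit$contrasts$estimate / fit$sigma, tolerance = 1e-12)
  # contrast t statistics carry the same containment df
  expect_true(all(fit$contrasts$df == 191))
})

test_that("duplicating every subject's rows leaves EMM estimates unchanged", {
  occ <- study_occupancy(2)
  fit1 <- fit_occupancy_lme(occ)
  doubled <- rbind(as.data.frame(occ), as.data.frame(occ))
  fit2 <- fit_occupancy_lme(doubled)
  expect_equal(fit2$contrasts$estimate, fit1$contrasts$estimate,
               tolerance = 1e-8)
})

test_that("with subject heterogeneity the LME F equals the blocked ANOVA F", {
  # balanced design with a clear subject effect (interior variance estimate):
  # the containment F for the interaction must reproduce the classical
  # within-subject (subject-blocked) two-way ANOVA stratum F
  d <- withr::with_seed(3, {
    g <- expand.grid(subject = sprintf("S%02d", 1:15),
                     condition = c("pre_rest", "task", "post_rest"),
                     state = factor(1:5), stringsAsFactors = FALSE)
    cond_eff <- c(pre_rest = 0.01, task = -0.01, post_rest = 0)
    state_eff <- c(0.1, -0.05, 0.2, -0.1, -0.15)
    subj_eff <- stats::setNames(rnorm(15, 0, 0.08), sprintf("S%02d", 1:15))
    g$proportion <- as.numeric(0.2 + cond_eff[g$condition] +
      state_eff[as.integer(g$state)] + subj_eff[g$subject] +
      rnorm(nrow(g), 0, 0.05))
    g
  })
  fit <- fit_occupancy_lme(d, contrasts = FALSE)
  aov_fit <- stats::aov(proportion ~ condition * state + Error(subject),
                        data = transform(d, subject = factor(subject),
                                         condition = factor(condition)))
  tab <- summary(aov_fit)[["Error: Within"]][[1]]
  f_aov <- tab["condition:state", "F value"]
  expect_equal(fit$interaction$F, f_aov, tolerance = 1e-6)
  expect_equal(fit$interaction$df_num,
               tab["condition:state", "Df"])
})

test_that("degenerate designs are rejected with informative errors", {
  occ <- study_occupancy(4)
  solo <- as.data.frame(occ)
  solo <- solo[!(solo$condition == "task" & solo$subject != "S01"), ]
  expect_error(fit_occupancy_lme(solo), "fewer than 2 subjects")
  gap <- as.data.frame(occ)
  gap <- gap[!(gap$condition == "task" & gap$state == 2), ]
  expect_error(fit_occupancy_lme(gap), "state=2")
  expect_error(fit_occupancy_lme(occ[occ$condition == "pre_rest", ]),
               "at least 2 conditions")
})

test_that("planted condition-by-state shifts are detected in the right direction", {
  profiles <- rbind(
    pre_rest  = c(0.172, 0.140, 0.381, 0.138, 0.167),
    task      = c(0.172, 0.188, 0.251, 0.221, 0.165),
    post_rest = c(0.168, 0.188, 0.294, 0.153, 0.194))
  profiles <- profiles / rowSums(profiles)
  occ <- study_occupancy(5, profiles)
  fit <- fit_occupancy_lme(occ)
  c3 <- fit$contrasts[fit$contrasts$state == 3 &
                        fit$contrasts$contrast == "pre_rest - task", ]
  expect_gt(c3$estimate, 0)  # less state-3 time during the task
  expect_lt(c3$p_raw, 0.05)
})
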