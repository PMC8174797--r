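# dfcstates

Dynamic functional-connectivity (DFC) states from sliding-window
correlations of regional fMRI time series.

Resting and task fMRI coupling between brain networks reorganizes on the
scale of tens of seconds. Given per-scan ROI time series for a 10-region
parcellation spanning the dorsal attention (DAN), default mode (DMN) and
frontoparietal (FPN) networks, this package estimates the recurrent
whole-matrix connectivity patterns ("states") that the scans revisit, and
tests whether experimental conditions differ in how long subjects spend in
each state. It is written for researchers analysing extracted ROI time
series (image preprocessing and ROI extraction are upstream and out of
scope) and for methodologists who want a fully seeded, simulation-validated
reference implementation of the sliding-window + k-means state pipeline.

## The method

For each scan, windows of width $w$ = 30 s are slid in steps of $s$ = 15 s
(converted to TR units per scan; fractional steps are realized with
alternating integer starts). In window $t$ the Pearson correlation
$r_{ij}(t)$ between every ROI pair is Fisher-transformed,
$z_{ij}(t) = \operatorname{atanh} r_{ij}(t)$, giving a symmetric
$10 \times 10$ matrix whose 45 upper-triangular entries form the window's
feature vector. Pooling all scans, k-means with Euclidean distance and
seeded restarts minimizes

$$\sum_{t} \lVert \mathbf{z}(t) - \boldsymbol{\mu}_{c(t)} \rVert^2 ,$$

and the centroids $\boldsymbol{\mu}_1, \dots, \boldsymbol{\mu}_k$ are the
DFC states. The number of states is chosen by a majority vote of ten
cluster-validity indices (silhouette, Calinski–Harabasz, Davies–Bouldin,
point-biserial, Krzanowski–Lai, Hartigan, Ball–Hall, Scott–Symons,
Friedman, Rubin). Each window's nearest centroid yields per-scan label
sequences, from which fractional occupancy (time proportion per state),
transition counts and dwell runs follow. Condition effects on occupancy are
tested with a linear mixed model (`nlme`), fixed condition-by-state
effects, random subject intercepts, containment df, and Bonferroni-adjusted
estimated-marginal-mean contrasts (`emmeans`). States of two solutions are
compared by optimal assignment on the centroid correlation matrix.

A synthetic-cohort generator with five planted covariance blueprints and
Markov state switching reproduces the emulated study design (15 subjects;
rest 300 volumes @ TR 2.0 s, task 804 volumes @ TR 1.5 s, one missing
post-task scan) and provides ground truth for every recovery test.

## Worked example

```r
library(dfcstates)

cohort <- simulate_cohort(cohort_design(seed = 1))   # 44 scans, ground truth
fit <- dfc_states(cohort, k = 5, seed = 1)           # or k = "auto"
summary(fit)
```

```
DFC state fit: k = 5, 2316 windows (post_rest = 546, pre_rest = 585, task = 1185)
Mean fractional occupancy (condition x state):
              1     2     3     4     5
post_rest 0.145 0.288 0.136 0.115 0.317
pre_rest  0.191 0.097 0.164 0.150 0.397
task      0.177 0.216 0.105 0.215 0.286
State sizes: 401, 470, 295, 406, 744 ; inertia 8421
```

The 15 rest scans contribute 39 windows each and the task scans 79, hence
585 + 1185 + 546 = 2316 pooled windows. States are numbered by decreasing
mean absolute centroid z, so the sparsest (low-connectivity) pattern gets
the highest label. Matching the fitted centroids to the planted blueprints
confirms which is which:

```r
match_states(fit$solution, blueprint_features(default_blueprints()))
```

```
State matching (k = 5), total r = 4.942
  state1 -> 1: r = 0.962, p = 6.69e-26, 95% CI [0.932, 0.979]
  state2 -> 2: r = 0.998, p = 5.41e-54, 95% CI [0.997, 0.999]
  state3 -> 5: r = 0.998, p = 6.97e-53, 95% CI [0.996, 0.999]
  state4 -> 4: r = 0.993, p = 5.97e-42, 95% CI [0.988, 0.996]
  state5 -> 3: r = 0.991, p = 6.45e-39, 95% CI [0.983, 0.995]
```

Every planted state is recovered with r > 0.96; the planted
low-connectivity state 3 is fitted state 5. The mixed model then tests the
planted condition effect (less time in the low-connectivity state during
the task):

```r
lme <- fit_occupancy_lme(fit$occupancy, family_size = 5)
lme$interaction
#> F(8, 191) = 5.0994, p = 9.143e-06
lme$contrasts[lme$contrasts$state == 5, ]
#>  state             contrast estimate      t   p_raw  p_adj cohen_d
#>      5      pre_rest - task   0.1105  2.780 0.00597 0.0299   1.015
#>      5 pre_rest - post_rest   0.0797  1.971 0.05014 0.2507   0.733
#>      5     task - post_rest  -0.0308 -0.761 0.44769 1.0000  -0.283
```

The planted ~0.13 occupancy drop between pre-task rest and task is
recovered (estimate 0.11, Bonferroni-adjusted p = 0.03, d ≈ 1.0); the
rest–rest contrast is not significant, as planted. `plot(fit)` draws the
five centroid heatmaps; `run_dfc_pipeline(cohort, "out/")` writes
centroids, assignments, occupancy, transitions and the statistical report
to a run directory; `compare_parcellations(fit_a, fit_b)` formats the
state matching between two runs.

## Limitations

Windowed correlations at 15–20 TR are noisy estimators, so validity-index
majorities for the number of states are genuinely weak (see the methods
vignette); and because occupancies are compositional, the mixed model's
interaction F is anticonservative under realistic sampling — its p-values
should be read as approximate. Both points are quantified in
`vignettes/dfc-states.Rmd`.
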