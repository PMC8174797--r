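---
title: "Estimating dynamic functional-connectivity states: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating dynamic functional-connectivity states: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfcstates)
```

## The model

Functional connectivity (FC) between brain regions is not constant over a
scan: coupling patterns reorganize on the scale of tens of seconds. The
sliding-window approach estimates this dynamic by computing, inside a short
window slid along the scan, the Pearson correlation between every pair of
regional time courses. `dfcstates` operates on a fixed 10-ROI parcellation
spanning three attention-related networks — dorsal attention (DAN: bilateral
intraparietal sulcus), default mode (DMN: MPFC, PCC, bilateral lateral
parietal) and frontoparietal (FPN: bilateral lateral prefrontal and posterior
parietal) — so each window yields a symmetric $10 \times 10$ correlation
matrix, variance-stabilized entrywise by the Fisher transform
$z = \operatorname{atanh}(r)$. The diagonal is undefined by convention and
never enters any computation.

A *connectivity state* is a recurrent whole-matrix pattern: windows from all
subjects and conditions are pooled, each matrix is flattened to its 45
upper-triangular z-values, and k-means with Euclidean distance partitions the
pooled windows into $k$ clusters. Cluster centroids are the states; each
window's nearest centroid classifies 30 s of scan time to one state. From
the per-scan label sequence follow the three summary statistics the package
reports:

* **fractional occupancy** — the fraction of a scan's windows assigned to
  each state (rows over states sum to 1 per scan);
* **transitions** — counts of consecutive-window label pairs, including
  self-transitions, plus dwell runs (maximal constant-label stretches);
* **condition contrasts** — a linear mixed model on the occupancy table.

## Window arithmetic

Windows are specified in seconds (default 30-s width, 15-s step) and
converted to repetition-time (TR) units per scan, so scans with different
TRs share the same temporal geometry. The width in TRs is
$\mathrm{round}(w/\mathrm{TR})$; window $i$ ($i = 0, 1, \dots$) starts at TR
$\mathrm{round}(i \cdot s/\mathrm{TR})$ with half-up rounding, and windows
are placed as long as they fit. Fractional steps are therefore realized
exactly on average: at TR = 2 s the 15-s step is 7.5 TR and the integer
starts alternate by 8 and 7. Under the reference design (below) this yields
39 windows per 300-volume rest scan, 79 per 804-volume task scan, and
$15 \cdot 39 + 15 \cdot 79 + 14 \cdot 39 = 2316$ pooled windows.

Half-up rounding (rather than R's banker's rounding) is deliberate: it is
the only placement that realizes a fractional step as a strictly alternating
start increment.

Correlations of magnitude $\ge 1 - 10^{-7}$ are clipped to
$\pm\operatorname{atanh}(1 - 10^{-7})$ so that degenerate in-window signals
produce a large finite feature instead of an infinity; realistic values are
unaffected. Windows are rectangular (no taper) and never span scan
boundaries; constant columns inside a window are an error, not a silent NA.

## Choosing the number of states

`select_k_majority()` fits k-means over a candidate range (default 2–8) and
lets a panel of ten cluster-validity indices vote; the k with the most votes
wins, ties going to the smallest k. The panel mixes *level* indices, which
nominate the best absolute score (silhouette, Calinski–Harabasz,
Davies–Bouldin, point-biserial), with *hierarchy* indices, which nominate
where a criterion curve bends (Krzanowski–Lai, Hartigan, Ball–Hall,
Scott–Symons, Friedman's $\mathrm{tr}(W^{-1}B)$, Rubin's determinant ratio,
using first- or second-difference rules). The two families are deliberately
complementary: when clusters overlap — which windowed FC guarantees, since a
15–20 TR window estimates each correlation with an sd of roughly
$1/\sqrt{T-3} \approx 0.3$ — level indices drift toward small k while
difference indices still locate the kink in the within-cluster
sum-of-squares curve at the true k.

Two indices often seen in such panels are intentionally absent. The gap
statistic's one-standard-error rule degenerates at this sample size: with
thousands of windows the simulation SE of the reference curve is so small
that the stopping condition essentially never triggers and the rule returns
the largest candidate, even though the gap curve itself bends at the true k.
Dunn's index depends on the single-linkage minimum separation between
clusters, which is a noise statistic when clusters overlap. Adding either
would only contribute structurally predictable off-target votes.

On synthetic cohorts with the default planted states the majority rule picks
k = 5 in roughly three quarters of cohort realizations; when it misses, the
winning vote is usually 2–4 carried by the level indices, while
Krzanowski–Lai and Rubin find 5 almost without exception. This mirrors how
weak index majorities are on real windowed-FC data and is worth remembering
before trusting any single automatic k.

## State estimation, labelling, matching

`kmeans_states()` runs Lloyd k-means with `n_init = 25` random restarts of
`max_iter = 25` iterations, keeps the lowest-inertia solution, and derives
every restart from one explicit seed (default 20210528), so a fit is a pure
function of data + configuration. A restart whose initialization collapses
(duplicate centers or an empty cluster) is re-drawn — the restart is
re-initialized rather than patched. Single-start behaviour is available via
`n_init = 1`. After fitting, windows are re-assigned to their exact nearest
centroid (ties to the lowest label) and states are renumbered by decreasing
mean absolute centroid z, which makes the sparsest, lowest-connectivity
state always the highest-numbered and the labelling reproducible across
seeds. Features are clustered on raw z-values without per-feature
standardization: all 45 features already share the Fisher-z scale.

`match_states()` compares two solutions: it computes the $k \times k$
Pearson-correlation matrix between centroid z-vectors and finds the pairing
that maximizes total correlation via an exact shortest-augmenting-path
assignment solver (verified in the tests against brute-force enumeration of
all $k!$ pairings). Each matched pair is reported with r, a two-sided
p-value and a confidence interval over the 45 features — the quantitative
replacement for matching states by visual inspection, and the tool behind
`compare_parcellations()`.

## Occupancy statistics

`fit_occupancy_lme()` models the occupancy table with fixed
condition-by-state effects and a random intercept per subject, fitted by
REML with `nlme`; the interaction is tested with the model ANOVA using
containment degrees of freedom. Under the reference design (220 rows, 15
subjects, 15 fixed-effect parameters) the interaction test carries
F(8, 191)-style df. Post hoc estimated-marginal-mean contrasts between
conditions within each state come from `emmeans`; p-values are
Bonferroni-multiplied by an explicit `family_size` (default 5, one contrast
family per state — the family is a reported parameter, never inferred
silently), and each contrast carries a Cohen's d defined as the EMM
difference divided by the model residual SD. Missing cells (a subject
without one condition) are simply absent rows; nothing is imputed.

Two modelling caveats are documented rather than hidden. First, "subject by
condition" random structures are ambiguous in this literature; this package
uses a random intercept per subject, which under containment reproduces the
denominator-df structure implied by the reference design, and the
subject-within-condition alternative can be obtained by recoding the subject
factor. Second — a genuine limitation found while validating the package —
fractional occupancies are compositional: the k proportions of one scan sum
to 1, so each scan contributes only $k - 1$ free values, while the
containment df count all $k$. Simulation shows the consequence directly:
with occupancy tables generated from the package's own Markov label
sampler under a null with no condition effect, the nominal 5% interaction
test rejects in roughly 13–15% of replicates, whereas on data satisfying
the model's Gaussian assumptions it is nominal (5.2–5.4% in 500-replicate
runs). Interaction p-values on real occupancy data should therefore be read
as approximate; the package reports the model exactly as specified but the
vignette flags the anticonservativeness.

`response_occupancy_correlation()` closes the behavioural loop: Pearson
correlation, per state, between a per-subject response count and occupancy
in a chosen condition.

## The synthetic cohort

`simulate_cohort()` generates the package's reference design: 15 subjects,
three conditions — pre-task rest (300 volumes, TR 2.0 s), task (804
volumes, TR 1.5 s), post-task rest (300 volumes, TR 2.0 s) — with one
subject missing the post-task scan (44 scans). Five planted state
blueprints give the qualitative patterns: global integration with a
decoupled MPFC; DMN–FPN coupling against an anticorrelated DAN; a global
low-connectivity state; an FPN hemispheric split (right FPN with DMN, left
FPN with DAN); and DAN–FPN coupling against an anticorrelated,
internally tight DMN.

Design parameters, their defaults, and why:

* **Blueprint z-levels** (`z_high = 0.6`, `z_low = 0.05`, `z_anti = -0.3`,
  DMN-intra 0.8 in state 5): free design levels chosen for between-state
  separability, not empirical estimates, and labelled as such. Each
  blueprint's implied correlation matrix is repaired to the nearest
  positive-definite correlation matrix (`Matrix::nearPD`); construction
  fails if the repair moves any entry by 0.05 or more (the default levels
  move entries by at most ~0.01).
* **Planted occupancy profiles**: condition-specific state probabilities
  defaulting to the occupancy means of the emulated study design
  (pre-rest 0.172/0.140/0.381/0.138/0.167; task
  0.172/0.188/0.251/0.221/0.165; post-rest 0.168/0.188/0.294/0.153/0.194,
  renormalized), which plants the characteristic rest-to-task shift: less
  time in the low-connectivity state 3, more in the split-FPN state 4.
* **Markov switching with `dwell_mean_windows = 3`** (45 s at the 15-s
  step): the hidden state sequence is a first-order Markov chain
  $P = (1-a)I + a\,\mathbf{1}\pi^\top$ whose stationary law is the
  occupancy profile, with $a$ calibrated so the occupancy-weighted mean
  dwell matches the requested value. 45 s sits mid-range of dwell times
  reported for sliding-window FC states, and the resulting per-scan
  occupancy sampling sd (~0.10–0.15 for a 39-window rest scan) reproduces
  the effect-size regime of the emulated design, where a 0.13
  between-condition drop in one state's occupancy is detectable at
  $t \approx 3$ with 15 subjects.
* **Observation model**: given the state at each TR, signals are zero-mean
  Gaussian with the state's repaired correlation as covariance, then
  AR(1)-smoothed per ROI (`ar_coef = 0.3`) with variance-preserving
  weights — the simplest temporal structure under which windowed Pearson
  correlation remains a consistent estimator of the planted pattern.

What the generator deliberately does **not** emulate: hemodynamic
convolution, physiological noise, motion artifacts, between-subject
variation in the state patterns or in the occupancy profiles, and
voxel-level structure upstream of ROI extraction. Passing recovery tests on
this cohort therefore demonstrates that the estimation pipeline is correct
and well calibrated under its stated assumptions — not that real fMRI data
satisfy those assumptions.

Because the mean dwell (45 s) is close to the window width (30 s), roughly
half of all windows straddle a state transition. This is realistic, and it
is the main driver of both the window-label error rate (~20% against the
per-window majority state) and the weak index majorities discussed above.
Recovered centroids are far cleaner than labels: matched to the planted
blueprints they correlate at $r > 0.92$ per state, replicate cohorts agree
at $r > 0.99$, and condition-mean occupancies recover the planted profiles
with RMSE ~0.03.

## Numerical and degenerate-input policies

* Correlation clipping at $|r| = 1 - 10^{-7}$; `|r| > 1` is an error.
* Window placement uses half-up rounding; a scan shorter than one window is
  an error naming the offending length.
* Nearest-centroid ties break to the lowest state label, deterministically.
* k-means restarts that produce empty clusters are re-initialized (up to 20
  draws) before failing.
* The positive-definite repair failing its 0.05 tolerance is an error, not
  a warning: sampling from a strongly repaired blueprint would silently
  change the planted pattern.
* Degenerate statistical inputs (a condition with one subject, an empty
  condition-by-state cell, constant behavioural responses) are errors that
  name the offending cell.

## Problem sizes used by the test suite

The shipped tests run the full reference cohort (2316 windows) for the
end-to-end checks, 20 cohort replicates for the k-selection study, 500
replicates for the size of the interaction test (Gaussian null) and its
label-based robustness companion, and 200 replicates for the power of the
planted state-3 contrast; unit tests use 2–4-subject cohorts with shortened
scans. These sizes were chosen so the whole suite exercises every claim at
meaningful replication counts while remaining a routine desk run.
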