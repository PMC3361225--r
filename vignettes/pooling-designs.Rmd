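---
title: "Virtual pooling designs and classifier performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual pooling designs and classifier performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Pooling biological specimens — combining $p$ subjects into one measured
sample — cuts assay costs by a factor $1/p$ and damps between-subject
variability, which makes it attractive for omics biomarker studies with
tight budgets or scarce material. But a classifier trained on pooled
samples must still predict *individual* future subjects, and pooling
shrinks the effective training-set size from $n$ to $m = n/p$. `poolsim`
quantifies this trade-off by Monte-Carlo simulation: it generates mock
omics data, pools the training set virtually, and measures how
misclassification on individual test samples grows with pool size, under
feature selection and across six standard classifiers.

## Generative model

Each of $a$ features carries a biological value $z$ and is measured as
$y = z + \varepsilon$ with technical noise
$\varepsilon \sim N(0, \sigma_\varepsilon^2)$. Classes are balanced and
dichotomous; per feature,

$$X_{\text{control}} \sim N(0, \sigma^2), \qquad
  X_{\text{case}} \sim N(\gamma, \sigma^2),$$

where $\gamma = 0$ for null features and $\gamma \sim U(0.3, 0.4)$ for
markers, redrawn every replication and shared between that replication's
training and test sets. Values live on the natural-log scale, as
log-intensities or log-concentrations would. Two presets bracket common
designs:

| preset | $a$ | $n$/class | $\sigma^2$ | $\sigma_\varepsilon^2$ |
|--------|-----|-----------|------------|------------------------|
| human  | 1000 | 90 | 0.2 | $0.2^2$ |
| animal | 1000 | 30 | 0.1 | $0.2^2$ |

The human preset mimics larger, more heterogeneous clinical cohorts; the
animal preset mimics small, homogeneous inbred-strain experiments. Marker
features occupy the first `n_markers` columns — their position carries no
information (no classifier or filter sees the indices), and fixed
placement keeps the bookkeeping deterministic.

## Pooling

Physical pooling happens on the natural scale before measurement, so the
pooled value of a group $g$ of $p$ subjects is

$$y' = \log\!\Big(\tfrac{1}{p}\sum_{i \in g} e^{z_i}\Big) + \varepsilon_k,
  \qquad \varepsilon_k \sim N(0, \sigma_\varepsilon^2),$$

i.e. the *biological* values are exponentiated, averaged, and logged, and
the pooled measurement incurs exactly one fresh technical error — not the
average of $p$ measurement errors. The generator therefore retains $z$
separately from $y$ internally. Straight (log-scale) averaging would give
pooled biological variance exactly $\sigma^2/p$; the exp-average-log value
sits slightly above the straight mean (Jensen's inequality) but follows
the same variance-reduction law closely at these small variances, and the
package checks both properties.

Pool membership is a uniformly random class-pure partition, re-randomized
every replication; only exhaustive designs ($n = pm$) are accepted. With
pool size 1 both the plan and the pooling transform are exact identities
that consume no random numbers, so the $p = 1$ arm of a pooled experiment
is bit-for-bit the non-pooled pipeline.

## Pipeline

Each replication: draw $\gamma$, simulate one individual training set and
one individual test set (450 samples, balanced — the class split of the
test set is a package choice, consistent with the balanced generative
model); for each pool size, pool the training set; rank features on the
(pooled) training data by the equal-variance two-sample $t$ statistic;
keep the top $k \in \{10, 100, 1000\}$ (1000 = no selection); tune each
classifier by class-stratified internal 3-fold cross-validation on the
training data only; train at the chosen hyperparameters; and score the
fraction of individual test samples misclassified. Standard $k$-fold
cross-validation or bootstrap evaluation is deliberately unavailable:
future subjects arrive one at a time with unknown class, so a test set
can never consist of pooled samples, and only a separate individual-sample
test set gives an honest error estimate for a pooling design.

Rates are aggregated per (classifier × pool size × top-$k$) cell as the
mean over replications with the normal-approximation 95% interval
(mean ± 1.96·SE). Design comparisons use the two-sided Wilcoxon rank-sum
test on replicate rates — between pool sizes (per classifier and top-$k$)
and between feature-selection settings (per classifier and pool size) —
with raw p-values, no multiplicity correction. Both pairwise matrices are
exposed (`wilcoxon_pool_sizes()`, `wilcoxon_top_k()`) since either margin
can be of interest.

## Classifiers and tuning grids

* **SVM, linear and radial kernel** (`e1071`): soft margin
  $c \in \{0.1, 1, 5, 10, 50, 100, 500\}$; radial width
  $\gamma_{\text{rbf}} \in \{0.25, 0.5, 1, 2, 4\}$. Features are passed
  unscaled — the simulated log-scale values are already comparable across
  features — and the solver's remaining settings are the library defaults.
* **Random forest** (`ranger`): 1000 trees fixed; candidate features per
  split $\in \{4, 8, 16, 32, 64\}$, clipped to the number of selected
  features when $k < 64$.
* **$k$-NN** (implemented here): Euclidean distance; grid $1..k_{\max}$
  with $k_{\max}$ = min(top-$k$, smallest CV training-partition size),
  since a fold model cannot use more neighbours than it has samples.
  Voting ties fall back to the single nearest neighbour's class, making
  predictions deterministic — the usual randomized tie-break would defeat
  exact reproducibility.
* **Penalized logistic regression** (`glmnet`, ridge):
  $\lambda \in \{0.0625, \dots, 16\}$ stated for the objective
  $-\ell(\beta) + \tfrac{\lambda}{2}\lVert\beta\rVert_2^2$ with an
  unpenalized intercept; glmnet scales its penalty per observation, so the
  grid value is divided by $n$ internally. Convergence tolerance $10^{-8}$.
* **Nearest shrunken centroids** (implemented here): class centroids are
  standardized against the overall centroid by
  $m_k (s_j + s_0)$ — pooled within-class SD $s_j$, offset $s_0$ = median
  of the $s_j$, $m_k = \sqrt{1/n_k - 1/n}$ — soft-thresholded by
  $\Delta \in \{0.1, 0.25, 0.5, 1, 2, 5\}$, and un-standardized.
  Features whose differences vanish in every class stop contributing: the
  method performs internal feature elimination, which is why it is
  implemented in full rather than wrapped. Priors are uniform (balanced
  classes); prediction ties go to the first class level.

Tuning minimizes mean CV misclassification over the grid; ties break to
the earliest grid row (grids are ordered by increasing parameter value,
kernel width nested inside soft margin), so tuning is deterministic given
the fold assignment. Stratification of folds is required, not cosmetic:
an unstratified 3-fold split of the 12-pool animal design would routinely
produce single-class folds.

## Randomness and reproducibility

A master seed spawns one sub-seed per replication
(`replication_seeds()`); each replication runs entirely under its own
seed, so any replication is reproducible in isolation and a run manifest
(`emit_manifest()`) — config echo plus the seed list — suffices to rerun
any slice bit for bit. The random forest draws its seed from the
replication stream.

## Problem sizes in the test suite

The shipped tests exercise the full pipeline at reduced replication
counts (15–40 per experiment, against the 300 used for the headline
tables), chosen so the whole suite runs in minutes on one core while
keeping cell-level Monte-Carlo standard errors near 0.01. The
replication count is a convention of the original design, not a
structural constant, and `n_reps` is a first-class argument throughout;
at $R$ replications the standard error of a cell mean is roughly
$0.04/\sqrt{R}$ under the presets. The acceptance script
(`scripts/acceptance.R`) uses 50 replications per cell.

## What the generator does and does not emulate

Features are independent Gaussians with equal variance in both classes;
markers differ only in mean. Real omics data add feature correlations,
skewed and heavy-tailed distributions, batch effects, missing values, and
unbalanced classes — all outside this generator. Consequences: the
simulated difficulty of a cell depends only on $(n, p, \sigma^2,
\sigma_\varepsilon^2, \#\text{markers}, \gamma)$, and passing results
show that the *pipeline* behaves as designed under the stated model, not
that any particular real study would achieve these error rates.
Within-model conclusions (error grows roughly linearly with pool size;
feature selection helps; sample size outweighs the variance advantage at
these settings) transfer as qualitative guidance only.

## Known limitations

* Two classes only, balanced designs only, exhaustive pooling only
  ($n = pm$; no partial or overlapping pools, no unequal contributions).
* The pooled average uses noise-free biological values, mirroring a pool
  formed before the assay; pooling already-measured noisy values would
  mix $p$ technical errors instead and is not modelled.
* No probability calibration or multi-class support; the PAM threshold
  path is searched only on the printed grid.
* Runtime is dominated by the 1000-tree random forest inside 3-fold
  tuning (16 fits per cell-replication); plan replication counts
  accordingly.
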