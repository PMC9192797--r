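---
title: "Selecting the number of clusters in latent class cluster analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting the number of clusters in latent class cluster analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lccaselect)
```

## The model

`lccaselect` clusters categorical survey-style data with a latent class
model: a finite mixture of products of multinomial distributions. An
observation is a vector of responses $x_i = (x_{i1}, \dots, x_{iJ})$, where
item $j$ has $m_j$ categories. Class $k$ has prior probability $\pi_k$ and,
given the class, items are independent with
$P(x_{ij} = h \mid k) = \alpha_{kjh}$. The observed-data log-likelihood is

$$\ell = \sum_i \log \sum_k \pi_k \prod_j \alpha_{kj,x_{ij}}.$$

The latent class plays the role of the cluster label: the fitted posterior
responsibilities $\tau_{ik}$ give each observation a soft membership, and
the MAP assignment $z_i = \arg\max_k \tau_{ik}$ (ties to the lowest class
index) gives the partition that all downstream diagnostics use.

Conditional independence given the class is the model's key assumption.
Items that remain correlated *within* a class (e.g. two nearly duplicated
questionnaire items) push the model toward spurious extra classes; that
failure mode is one reason the package surfaces several selection criteria
rather than automating the choice of $K$.

## Fitting

`fit_em()` maximises $\ell$ by EM with random restarts.

* **Initialisation.** Each restart draws per-observation responsibilities
  from a symmetric Dirichlet(1) and starts with an M-step. Random
  responsibilities (rather than random parameters) avoid the early
  label-degeneracies that plague small-$\pi$ starts.
* **Restarts.** Default 20. The likelihood surface is multimodal; the best
  restart by final $\ell$ is kept, and the number of restarts is the main
  robustness dial. Functions that fit many models (bootstrap replicates)
  reduce it, as documented there.
* **Convergence.** Relative change $|\ell_t - \ell_{t-1}| \le
  \text{tol}\,|\ell_{t-1}|$ with tol $= 10^{-6}$, capped at 1000
  iterations.
* **Smoothing.** The M-step adds a vanishing pseudo-count
  $\varepsilon = 10^{-10}$ per category, which keeps every $\alpha$
  strictly positive (so $\ell$ stays finite on sparse categories) while
  leaving the updates maximum-likelihood to numerical precision — in
  particular the log-likelihood trace retains EM's monotonicity guarantee.
  A *larger* $\varepsilon$ was considered and rejected: it silently turns
  EM into a MAP procedure whose observed-data log-likelihood can decrease
  (we measured decreases of $\sim 10^{-4}$ at $\varepsilon = 0.01$ on
  adversarial random instances). The one place where near-zero fitted
  probabilities genuinely cause trouble — classifying the full sample
  under a model fitted on a bootstrap resample that missed every carrier
  of a rare category — is handled where it arises, by the bootstrap's
  classification smoothing (below), not by biasing every fit.
* **Degenerate classes.** A restart in which a class's total
  responsibility falls below $10^{-8}$ is abandoned and re-initialised (up
  to 3 extra attempts) instead of silently reducing $K$.
* **Determinism.** A single integer seed derives all per-restart
  substreams, so a fit is reproducible bit for bit.
* **Pattern aggregation.** Internally EM runs on the table of distinct
  response patterns with multiplicities — mathematically identical to
  per-row EM, but the number of distinct patterns in ordinal survey data
  is usually far below $n$, which is what makes the bootstrap and the
  selection sweep cheap.

Missing data are deliberately **not** handled inside EM. The workflow is
impute-then-cluster: explore missingness (`missingness_summary()`,
`missingness_plot()`), drop fully missing rows (`drop_empty_rows()`), and
impute (`impute_missing()`, a chained random-forest scheme with a 10-cycle
cap; observed cells are never altered). `icc_per_variable()` /
`icc_screen()` provide the usual one-way ICC screen for whether a
single-level model is defensible; codes are treated as numeric scores
there, which is conventional for screening but a documented approximation.

## Selection criteria

`selection_table()` fits $K = 1$ to $10$ (the conventional range for this
kind of analysis) and tabulates, per $K$:

* $\nu_K = (K-1) + K\sum_j (m_j - 1)$ free parameters;
* $\mathrm{BIC} = -2\ell + \nu \log n$ — deviance scale, *smaller is
  better*;
* the responsibility entropy $EN = -\sum_{ik} \tau_{ik}\log\tau_{ik}$;
* $\mathrm{ICL} = \mathrm{BIC} + 2\,EN$ — the entropy-penalised BIC, which
  favours well-separated classes; $\mathrm{ICL} \ge \mathrm{BIC}$ always,
  and both are minimised. (Published tables sometimes report ICL on a
  log-evidence scale where it is negative and "minimal" means closest to
  zero; the deviance convention here keeps both criteria on one scale.)
* the average silhouette width (ASW) of the MAP partition, undefined at
  $K = 1$.

**ASW.** The dissimilarity is simple matching (normalised Hamming): the
proportion of items on which two observations disagree. It is the
canonical choice for unordered category codes; users who want an
ordinal-aware metric can compute silhouettes on their own dissimilarity.
Members of singleton clusters get $s(i) = 0$ (the classical convention),
as do observations whose within- and between-cluster dissimilarities are
both zero. The production implementation computes all $s(i)$ from
per-cluster category counts in $O(nJK)$; the test suite checks it to
$10^{-12}$ against a full $O(n^2)$ pairwise oracle and against
`cluster::silhouette`.

**Elbow.** The elbow heuristic is formalised as the interior $K$
maximising the *relative curvature*

$$\frac{(\mathrm{BIC}_{K-1} - \mathrm{BIC}_K) - (\mathrm{BIC}_K -
\mathrm{BIC}_{K+1})}{\max(|\mathrm{BIC}_K - \mathrm{BIC}_{K+1}|,
\epsilon)},$$

ties to the smallest $K$. The design choice here is the denominator: a raw
second difference is dominated by the first drops of the curve — BIC
curves fall steeply from $K = 1$ essentially always, so the raw form
degenerates to "elbow at 2" — whereas the visual elbow sits where the
remaining improvement becomes negligible *relative to the bend*. On simple
curves the two definitions agree (e.g. $100, 80, 40, 38, 37 \to K = 3$; a
linear curve ties everywhere and yields the smallest interior $K$). The
elbow is advisory: the combined plot from `selection_plot()` (BIC panel
with min-BIC/min-ICL lines and the elbow marker; ASW panel from $K = 2$)
is the primary instrument.

## Stability

`bootstrap_stability()` judges whether a candidate solution survives
sampling noise. The scheme: fit a reference $K$-class model on the full
data; for each of $B$ replicates (default 100), resample $n$ rows with
replacement, refit, classify *all original* observations under the
replicate model, and compare that partition with the reference partition
by the adjusted Rand index and the pair-counting Jaccard coefficient. The
classify-the-full-sample choice avoids the ambiguity of overlap-only
comparisons and yields exactly one ARI and one Jaccard per replicate; both
are reported in full along with their means. Replicate fits reuse the fit
configuration with restarts reduced to `max(5, restarts %/% 4)`
(overridable) — the reference fit needs the global optimum, the replicates
only need the same basin. Before the full sample is classified, each
replicate model's item probabilities are mixed with a uniform distribution
(weight $10^{-3}$, the `classify_smoothing` argument): a resample that
happens to omit every carrier of a rare category would otherwise leave
that category's probability at the numerical floor ($\log\alpha \approx
-23$), a single cell that overrides every other item and flips rare
response patterns between replicates. That is resampling-noise artefact,
not instability of the solution, and the mixing weight (a tenth of a
percent) is far below anything the agreement indices can resolve
otherwise.

Both agreement indices are label-permutation invariant and equal 1 exactly
when two partitions coincide up to relabelling; the implementation works
from the contingency table, and the tests pin it to a brute-force
enumeration over all observation pairs.

## The synthetic-data generator

`simulate_ordinal_clusters()` draws ordinal clustered data from a
latent-Gaussian threshold model: an observation in cluster $k$ gets $J$
independent latent values $N(\text{offset}_{kj}, \text{sd}_k)$, and each
item is cut into $m$ ordinal categories at fixed global quantiles of its
pooled latent distribution. Separation is controlled by the offset
profiles relative to the within-cluster spread; unequal weights and
unequal spreads are supported and used by every preset. Cluster sizes are
allocated deterministically (largest remainder), and a single seed
reproduces the draw exactly.

The cut probabilities default to equal-mass bins but are a parameter
(`threshold_probs`). The preset designs align them with the cumulative
cluster masses: with unequal cluster weights, equal-mass cuts necessarily
slice through cluster cores, so every cluster straddles two categories on
every item — realistic for some instruments, but it flattens the
silhouette structure that the separated designs are meant to exhibit.
Aligned cuts place the category boundaries in the gaps between latent
blobs, so each separable cluster occupies essentially one category per
item. This also means preset marginal category frequencies are unequal,
mirroring the fact that real response options are not equally popular.

`preset_designs()` provides six regimes, named by generated/separable
cluster counts: A = 4/0 (all offsets zero), B = 4/3, C = 4/4,
D = E = 6/4, F = 6/6; A-C have $n = 1550$, D-F $n = 2250$, all with 6
items and 4 categories. Separable clusters sit on Latin-square level
profiles (every pair differs on most items); non-separable clusters sit a
fraction of a level off a base cluster's profile so their responses
straddle two categories and overlap it. B's fourth cluster straddles by
0.3 of a level, which also routes 30% of its mass into the category that
its three base clusters leave empty — every category of every item is
populated in every preset. F's fifth and sixth profiles were chosen by
maximising the minimum gap-weighted Hamming distance to the Latin rows,
which is what makes its six clusters jointly separable rather than merely
pairwise distinct.

What the generator does *not* emulate: within-class item dependence
(the data are generated exactly under the model's conditional-independence
assumption), covariate effects, informative missingness (it generates
complete data), and drifting category usage across subpopulations.
Passing tests on these presets therefore demonstrate that the selection
machinery behaves as designed *when the model family is correct and
separation is the only difficulty* — they do not certify behaviour under
model misspecification.

## Post-selection diagnostics

`cluster_report()` bundles what an analyst consults after shortlisting
solutions: population shares (clusters below 0.05 of the sample are
flagged; a tiny class is usually a symptom, not a discovery),
per-item discriminative power, silhouette values, and the standard
figures (item-probability plot with classes ordered by mean item score,
silhouette plot, and a principal-component view of the one-hot expansion
that carries its own caveat: 2-D projections of higher-dimensional
structure can mislead, silhouettes are the more reliable separation
diagnostic).

Discriminative power is the log ratio of the evidence that an item is
relevant versus irrelevant to the clustering given the partition: the
exact integrated multinomial marginal likelihood of the item computed
within clusters versus pooled, under a symmetric Dirichlet(1/2) prior,
via log-Gamma sums. It is implemented in the spirit of the variable-
selection literature's criterion, conditional on the MAP partition, not
as a replica of any package's internals; the prior is a parameter. A
single-cluster partition gives exactly 0 for every item; an item
independent of the partition typically scores below 0 (the extra
per-cluster parameters cost more evidence than they earn).

## Problem sizes in the checks

The validation suite runs the full pipeline at the presets' native sizes
($n = 1550$ and $2250$, $B = 100$ bootstrap replicates, selection sweeps
over $K = 1..10$ at 10 restarts, 20 seeded repetitions), which completes
in minutes because of the pattern-aggregated EM. Property checks (oracle
agreement, EM monotonicity, parameter recovery at $n = 2000$) use
randomized instances with fixed seeds. The ICC recovery check runs at 100
groups of 20, where the one-way estimator's sampling sd is about 0.03;
the test bounds the mean error rather than every seed's error for that
reason.

## Known limitations

* No ordinal-constrained (adjacent-category) parameterisation: categories
  are treated as unordered by the likelihood; ordinality enters only
  through the generator and the display order of classes.
* No covariates, no multilevel latent class model. The ICC screen tells
  you when the latter might be needed; the package then stops at a
  warning.
* The bootstrap scheme compares partitions on the full original sample;
  alternatives (out-of-bag, overlap-only) answer slightly different
  questions and are out of scope.
* Model-based criteria inherit the conditional-independence assumption;
  locally dependent items inflate the apparent number of classes, and no
  criterion here diagnoses that directly.
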