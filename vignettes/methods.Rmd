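---
title: "Directed brain-network analysis with gcnet: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed brain-network analysis with gcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gcnet builds directed and undirected functional brain networks from
region-of-interest (ROI) time series, reduces them to binary graphs,
extracts topology features, ranks candidate hub regions, and classifies
subject groups. This vignette is the package's account of the underlying
models, the conventions and tunable parameters, what the synthetic cohort
generator does and does not emulate, and the design decisions taken where
more than one convention was defensible.

## The signal model

Each subject is an `roi_ts`: a regions × samples matrix (116 regions under
the AAL116 parcellation is the canonical geometry; 20 regions is the
default for synthetic validation work), with a sampling rate of 500 Hz and
2 s analysis epochs of 1000 samples by default. `segment_epochs()` cuts
non-overlapping epochs and discards the trailing partial epoch;
`select_representative()` implements maximal-total-power signal selection
(exposed for completeness — its natural inputs, per-region source dipole
signals, arise upstream of this package's scope). All connectivity
estimation is preceded by `zscore()`, population-convention row
standardization, purely as numerical conditioning: Granger causality and
Pearson correlation are both invariant to affine per-channel rescaling.

A recording is analyzed either as a single segment (the default — a
116 × 1000 matrix is exactly one 2 s epoch at 500 Hz) or in multi-epoch
mode (`epoch_seconds` in `cohort_connectivity()`), in which connectivity
is estimated per epoch and averaged with `aggregate_epochs()`. Averaging
over E epochs shrinks the sampling noise of every matrix entry by roughly
√E while leaving systematic structure unchanged.

## Directed connectivity: pairwise Granger causality

For an ordered region pair (Y, X), two nested least-squares models of X
are fitted on a common effective window (the first p samples dropped):

* reduced: X_t on its own p lags;
* full: X_t on p lags of both X and Y.

With maximum-likelihood residual variances σ′² (reduced) and σ² (full),
the causality measure is F(Y→X) = ln(σ′²/σ²). Three conventions matter
and are deliberate:

* **ML variance divisor (1/n_effective).** Nested least squares
  guarantees σ′² ≥ σ², hence F ≥ 0 exactly; unbiased divisors can produce
  negative F. Roundoff below 1e-8 is clamped to zero; anything larger
  raises an error.
* **Common effective window.** Both models use the same target samples, so
  the variances are comparable.
* **Pairwise, not conditional.** The full multivariate alternative (every
  region conditioned on all others) is not identifiable at the canonical
  scale: an order-5 model of 116 regions has 580 coefficients per equation
  against 1000 samples. Bivariate models are identifiable and are what the
  estimator implements; conditional and spectral Granger variants are
  out of scope.

The lag order is either fixed or selected by `select_order_bic()`:
full-model BIC, `n_eff · ln det(Σ̂) + k · ln(n_eff)` with k = p·n² free
coefficients, evaluated for p = 1..10 on a common window (the last
n − max_order samples) so the criteria are comparable; ties go to the
smaller order. On realizations of the packaged five-channel order-5
reference process (`mvar5_demo_spec()`), the selected order is 5 in
essentially every seeded replicate.

Undirected connectivity is the Pearson correlation matrix (`pearson_matrix()`)
with a zeroed diagonal.

## Normalization and binarization

`normalize_weights()` maps each subject's matrix to [0, 1]: Pearson
weights are rectified to absolute values first (a threshold needs a
nonnegative strength ordering; whether negative correlations should
instead be zeroed is genuinely open, and rectification is the
documented choice), then all off-diagonal weights are divided by the
subject's maximum off-diagonal magnitude.

`proportional_binarize()` retains the k = floor(psw · M) strongest
off-diagonal weights (M = n(n−1) directed, n(n−1)/2 undirected with
mirroring). floor() never exceeds the requested cost. Ties break by
weight, then row, then column index, which makes thresholds deterministic
and nested: the edge set at a smaller psw is always a subset of the set at
a larger one.

The retained proportion is chosen by global-cost-efficiency maximization:
GCE(psw) = E(psw) − psw, where E is the global efficiency of the
binarized graph. `select_threshold()` evaluates the grid 0.05–0.50 in
steps of 0.05, averages GCE across all subjects of a method, and applies
the single argmax threshold to everyone — a group-level selection,
because one optimum per method (not per subject) is what downstream
group comparisons require. Ties go to the sparser threshold; infeasible
grid points (k = 0) are skipped with a recorded warning.

## Graph topology features

On each binary network, `feature_vector()` produces 4 + 4n features
(468 when n = 116), ordered [GCC, GCLP, GE, GLE] then one
[NCC, NE, NLE, NDC] block per region in label order:

* **Distances** are unweighted shortest paths following edge direction.
  Unreachable pairs contribute 0 to efficiencies (1/∞) and are excluded
  from the characteristic path length, the two standard conventions that
  keep both finite; a graph with no reachable pair has no defined GCLP and
  raises an error rather than returning a made-up value.
* **Clustering** uses Fagiolo's directed generalization — all directed
  triangle motifs through a node over the corrected possible count,
  [(A+A′)³]ᵢᵢ / (2[d_tot(d_tot−1) − 2d_bi]) — or the standard undirected
  form. Both are cross-checked against exhaustive triangle enumeration in
  the test suite.
* **Local efficiency** of a node is the global efficiency of the subgraph
  induced by the union of its in- and out-neighbors (0 with fewer than 2
  neighbors), with distances computed inside the subgraph only.
* **Degree centrality** is in-degree + out-degree for directed networks;
  out-degree only is available via `ndc_mode = "out"`.

GCC and GLE are exact means of their nodal counterparts, asserted as
identities in the tests.

## Hub analysis

Four rankings are computed from group-mean normalized directed matrices:
the 20 strongest connections (LCS), the 20 most group-dissimilar
connections by |patient − control| with sign retained (GDC), the 5
regions with the highest out-strength, i.e. row sums of the weighted
matrix (HODR), and the 5 regions with the most dissimilar out-strength
(GDR). `hub_consensus()` counts, per region, in how many of the four
lists it appears — edge lists contribute both endpoints, at most once per
list, so one dominating list cannot inflate a region's count — and
reports regions appearing in ≥ 2 lists as hubs. The ≥ 2-of-4 rule
operationalizes "consistent prominence across multiple metrics"; the
threshold is a parameter.

## Group statistics and classification

Per-feature group differences use a normality-gated test: each sample is
screened by a one-sample Kolmogorov–Smirnov test against a normal with
its own fitted mean and standard deviation; if both groups pass at
α = 0.05 an unpaired t-test is used, otherwise a Mann–Whitney U test
(exact when both n ≤ 20 without ties, tie-corrected normal approximation
otherwise). Estimating the null's parameters from the sample makes the
K-S screen conservative (the Lilliefors correction is documented but not
applied, keeping the plain K-S gate).

Classification screens features by Mann–Whitney U at α = 0.05 with no
multiple-testing correction (a Benjamini–Hochberg flag exists but is off
by default), then trains a linear SVM (unit cost, kernel and cost
exposed) on a stratified 70/30 split with round-to-nearest per-class
counts — 34 patients and 14 controls split into 24 + 10 training and
10 + 4 validation subjects. Standardization uses training-set statistics
only, and by default the Mann–Whitney screen also sees only training
rows. `paper_mode = TRUE` screens on all subjects instead, reproducing a
protocol common in the applied literature; it leaks validation
information into feature selection and is off by default. Reported
metrics: accuracy, precision, recall, F1, Cohen's kappa (computed from
the confusion table's closed form) and ROC-AUC from the SVM decision
values.

`order_sweep()` rebuilds the entire directed pipeline at each lag order
1–10 and classifies with a fixed split seed, optionally averaging over
`n_repeats` repeated splits; orders at which no feature passes the screen
are reported with zero features and NA metrics rather than aborting the
sweep.

## The synthetic cohort generator

Because no clinical recordings ship with the package, validation rests on
stationary multivariate autoregressive (MVAR) simulation with known
ground truth. `simulation_spec()` enforces stationarity (companion-matrix
spectral radius < 1) and innovation-covariance positive-definiteness;
`simulate_mvar()` runs the recursion from a zero state and discards a
500-sample burn-in, which removes the initialization transient.
`ground_truth_graph()` exposes the true directed edge set for recovery
tests; ranking pairwise-GC weights against it attains ROC-AUC > 0.95 on
10-node order-3 processes with planted gain-0.4 edges at n = 1000.

Two-group cohorts (`cohort_spec()`, `make_cohort()`) plant a group
difference as an additive increment on designated coupling coefficients —
an effect on connection strength, not on noise power, because elevated
directed coupling is the phenomenon of interest. The increment is applied
at the base process's highest lag by default, so models of too low an
order cannot express the group difference. Per-subject seeds derive
deterministically from the cohort seed (`seed·1009 + index·9973` mod
2³¹−1), giving reproducibility with subject independence. Default group
sizes are 14 vs 34 (48 subjects), matching the canonical cohort
arithmetic used throughout the classification stage.

`demo_cohort_spec()` freezes the package's reference validation cohort:
20 regions, order-5 base dynamics with lag-1 self-memory and two short
feed-forward coupling chains, and a patient effect of +0.3 on five
feed-forward edges from three hub sources onto five otherwise-uncoupled
sink regions at lag 5. The acyclic hub→sink design is deliberate: each
(source, sink) pair is then exactly a bivariate VAR(5), so the effect is
cleanly expressible at order 5 and invisible below order 4, and the three
source regions are recoverable as consensus hubs. The effect size itself
is a free parameter chosen for test power; no empirical estimate of the
clinical coupling increase exists to calibrate it against.

What the generator does **not** emulate: MEG sensor physics, source
leakage and field spread, 1/f spectra, nonstationarity, oscillatory
rhythms, or artifacts. Passing the synthetic validation therefore shows
that the estimator chain is correct and sensitive under its own model
assumptions — not that comparable performance is expected on clinical
recordings.

## Validation results and a known limitation

The packaged tests verify, among others: exact agreement of GC matrices,
distances, clustering and efficiencies with independent brute-force
implementations; BIC recovery of generating orders 2 and 5; recovery of
the theoretical F = ln(1.81) for a gain-0.9 unidirectional coupling;
planted-effect recovery (patient mean raw GC strength above controls in
every replicate, end-to-end validation AUC above 0.8 averaged over 10
cohort seeds at the generating order, and null-cohort AUC
indistinguishable from 0.5). Group strength comparisons use the raw
(unnormalized) causality matrices: per-subject max-normalization divides
a patient's entire matrix by their inflated strongest edge, so for a
concentrated planted effect the *normalized* mean strength can move
opposite to the true coupling change — a property worth remembering when
interpreting normalized averages on real data too.

One documented limitation: on these linear Gaussian cohorts the
best-classifying lag order is not sharply localized at the generating
order. Classification at orders 5–6 clearly beats orders 1–3 (which
cannot express a lag-5 effect), but performance does not degrade at
orders 7–10 the way one might expect from overfitting: proportional
thresholding is rank-based, so a noise floor that rises uniformly with
order barely perturbs edge rankings, and the bivariate marginals of a
multivariate VAR are VARMA processes whose reduced models genuinely keep
improving past the generating order. The best-AUC order is consequently a
diffuse draw from the ≥ 5 plateau rather than a point at 5. The sweep's
acceptance test records both facts: the low-vs-correct order contrast
(robust) and the strict localization of the argmax in {4, 5, 6}
(not achieved under these conditions).

## Problem sizes used in the packaged tests

Unit tests run on 3–20 region processes with 200–1000 samples; oracle
equivalence uses ≤ 10-node graphs; the end-to-end cohort checks use the
20-region reference cohort at n = 1000 with 10 seeded replicates, and the
order sweep uses 10 replicates × 10 orders with 10 repeated splits each.
These sizes were chosen so the full validation runs comfortably on a
laptop; the same functions scale unchanged to 116 regions.
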