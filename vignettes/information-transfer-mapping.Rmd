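---
title: "Information transfer mapping: model, estimators, and the simulated validation bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information transfer mapping: model, estimators, and the simulated validation bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infoflow)
```

## The question the package addresses

Multivariate pattern decoding shows that many brain regions carry task
information in their fine-grained activation patterns, but decoding alone is
an experimenter-as-receiver exercise: it says nothing about whether *other
brain regions* can use that information. `infoflow` implements a
cortex-as-receiver analysis — information transfer mapping — which asks
whether the resting-state functional-connectivity (FC) topology between two
regions forms an information-preserving channel.

The procedure has three steps per ordered (source, target) pair:

1. **Activity flow mapping.** The target's activation pattern for miniblock
   $k$ is predicted as a dot product through the resting-state FC weights,
   $\hat{B}_k = A_k \cdot W_{\mathrm{RSFC}}$, where $A_k$ is the source
   pattern and $W_{\mathrm{RSFC}}$ the source-by-target block of FC weights
   (`activity_flow_map()`).
2. **Cross-validated representational similarity.** Each predicted pattern
   is compared (spatially demeaned, Fisher-z Spearman correlation) with
   *actual* condition prototypes of the target region, built with the
   evaluated block's fold held out (`condition_prototypes()`, `cv_folds()`).
3. **Match minus mismatch.** The transfer estimate is the mean correlation
   with the matching condition's prototype minus the mean correlation with
   the mismatching prototypes. Positive values mean the mapped pattern still
   encodes which condition occurred — chance decoding gives zero
   (`info_transfer_estimate()`).

The same match-minus-mismatch statistic applied to a region's own patterns
(no mapping) is the baseline information estimate
(`information_estimate()`).

## Connectivity estimation

FC weights are regression coefficients, not correlations. For each target
node $i$, `multreg_fc()` fits
$x_i = \beta_0 + \sum_{j \neq i} \beta_{ji} x_j + \varepsilon$ by ordinary
least squares and stores $\beta_{ji}$ at row $j$, column $i$ of the
source-by-target matrix. These are semipartial estimates: they isolate
unique shared variance (suppressing indirect paths) and retain the scaling
of each source into the target's units, which is exactly what a linear
activity-flow prediction needs. The solver is QR-based least squares on
per-node demeaned series, never explicit normal equations; rank deficiency
and under-determined systems (timepoints ≤ nodes) are hard errors naming
the offending nodes.

When sources outnumber timepoints (vertex-level analyses), `pcreg_fc()`
regresses the target on the leading principal components of the masked
source matrix (500 components in the empirical setting) and back-projects
the coefficients; sources excluded by a spatial-proximity mask are removed
*before* component extraction and receive a coefficient of exactly 0. At
full component count on full-rank data it reproduces the OLS solution,
which the tests assert.

Between-network global connectivity (`bgc()`) summarizes hubness:
$\mathrm{BGC}_i = \sum_{j \notin C(i)} W_{ij} / (N_{\mathrm{total}} -
N_{C(i)})$, the mean FC from node $i$ to all nodes outside its own network.

## Task activations

`estimate_betas()` fits one boxcar regressor per miniblock — not per
condition — convolved with the canonical double-gamma HRF, jointly with an
intercept and optional nuisance regressors. Condition labels attach to the
resulting miniblock-by-node beta matrix afterwards, so the same activation
set serves every rule domain. Regressors are built on a 16-fold oversampled
grid and decimated to the TR grid, mirroring the forward model used by the
simulator. A variance-inflation diagnostic warns when convolved blocks are
too collinear for block-wise estimation; no autocorrelation correction is
applied (configurable in principle, deliberately out of scope here).

## The simulated validation bed

Because no empirical data can certify a *ground-truth* information channel,
the package ships a firing-rate network simulator whose connectivity is
known by construction.

**Topology.** 250 nodes in five communities of 50. Directed edges are
sampled independently per ordered pair: density 0.35 within a community,
0.05 between, except that edges *from* one designated hub community to the
rest are sampled at 0.20. Gaussian synaptic weights on existing edges have
mean $1/\sqrt{K_i}$ and sd $0.2/\sqrt{K_i}$, with $K_i$ the receiver's
realized in-degree, so total input scales with the number of inputs — a
scaling rule observed in vitro in balanced cortical cultures.

**Dynamics.** Each node follows
$\tau \dot{x}_i = -x_i + s\,\phi(x_i) + g \big(\sum_{j \neq i} W_{ij}
\phi(x_j) - \bar{W}_i \bar{\phi}\big) + I_i(t)$, with $\phi = \tanh$,
$\tau = 10$ ms, integrated by the explicit midpoint (RK2) method at
$dt = 10$ ms from $x(0)=0$, with a 10 s burn-in discarded. $I_i(t)$ is
fresh unit-variance Gaussian noise per node per step (held constant across
the two stage evaluations — the input is treated as piecewise-constant
external drive, not as an Itô term), plus constant-amplitude stimulation
during task blocks.

Two choices here complete the model where a purely excitatory reading is
not viable, and they deserve emphasis:

- **Balanced coupling** (the $-\bar{W}_i \bar{\phi}$ term, `balanced_coupling`):
  with all-positive mean-$1/\sqrt{K}$ weights the unbalanced network has a
  total drive of order $\sqrt{K} \approx 6$, which pins every node at a
  saturated fixed point where $\phi' \approx 0$ — no fluctuation
  transmits, and rest-FC is blind to the topology. Subtracting each node's
  total in-weight times the network-mean activation is the standard
  balanced-network completion (the same physiology that motivates the
  $1/\sqrt{K}$ rule): it removes the common-mode runaway while leaving the
  community-structured modes, which carry the topology, untouched.
- **Global coupling $g = 0.3$** (default): linear stability of the
  balanced network's community modes requires $g$ below the reciprocal of
  the leading community eigenvalue (within-degree × mean weight ≈ 2.9, so
  $g < 0.35$). At $g = 1$ the balanced network freezes into quenched
  saturated patterns whose time-fluctuations again carry no topology; at
  very small $g$ the coupling is too weak to shape correlations. The
  default sits just inside the stable near-critical band, where slow
  community-coherent fluctuations survive hemodynamic filtering. This is a
  deliberate deviation from taking the local and global gains both equal
  to one, which is dynamically inoperable for this weight rule.

**Hemodynamics.** `to_bold()` convolves each node with the canonical
double-gamma HRF (peak 6 s, undershoot 16 s, dispersions 1 s, ratio 6,
32 s support, unit peak) sampled at the neural rate, then decimates to a
1 s TR by taking the last convolved sample of each interval (simple
decimation, not windowed averaging). Rest runs last 600 s → 600 BOLD
samples.

**Task.** Four conditions stimulate four disjoint, randomly drawn 12-node
subsets of the hub community. Defaults: amplitude 0.5 (same order as the
noise), 10 s blocks separated by 10 s rest, 32 blocks per condition (128
miniblocks, matching the condition-rich miniblock count of the task
paradigm the simulation emulates), condition order randomized within each
cycle of four. Amplitude and block layout stand in for unavailable
published detail and are exposed in `sim_config()`; note that the transfer
estimate is invariant to rescaling the stimulation (both the mapped signal
and the mapped FC noise scale together), so this choice mostly affects GLM
signal-to-noise, which is already high at the defaults.

**What the generator does and does not emulate.** It reproduces
community-structured connectivity with a known hub, stochastic rest
dynamics, condition-specific task drive, hemodynamic blurring and TR
sampling. It does not emulate scanner noise, motion or physiological
artifacts, spatial autocorrelation of vertices, task-state FC changes, or
inter-subject anatomical variability — so green validation tests certify
the estimators' behavior under the model's assumptions, not performance on
real scans.

## The validation experiment

`run_validation()` simulates a group (30 subjects by default, each an
independent network realization), runs rest → `multreg_fc()`, task →
`estimate_betas()`, per-network `bgc()`, and all 20 ordered
network-to-network transfers, then applies group inference: one-sided
one-sample t-tests across subjects per pair with max-statistic sign-flip
FWE correction (`fwe_maxstat()`), and paired t-tests of hub BGC against
each other network. The ground-truth expectations are:

- transfers on pairs involving the hub carry information (positive
  estimates, significant after FWE);
- transfers among the four non-hub networks sit at chance;
- the hub network has the highest BGC in essentially every subject.

A further specificity check (`fc_permutation_test()`) recomputes transfer
estimates after permuting the target-node columns of the FC block — a
topology-destroying, scale-preserving null. Estimates driven by the actual
fine-grained FC pattern collapse to zero under this null; the scheme
(column, row, or full shuffle) is configurable because the exact published
construction is not specified in the available text.

At these defaults the experiment yields hub-involving transfer estimates
around 0.04–0.05 with an averaged group t above 6 (all hub pairs
FWE-significant), non-hub means within ±0.01 of zero with no significant
pairs, and hub-vs-other BGC paired t-statistics in the tens. The *contrast*
is the validated object; the absolute transfer magnitude depends on the FC
estimation noise at 600 rest samples and on the operating regime of the
dynamics, and is accordingly reported, not tuned.

## Group statistics and behavioral decoding

`group_ttest()` provides one-sample t-tests per comparison;
`fwe_maxstat()` implements max-statistic FWE correction with row sign-flips
(1000 permutations by default; the corrected p floor is $1/(n_{\mathrm{perm}}+1)$,
and the uncorrected p it reports comes from each comparison's own sign-flip
null so that corrected ≥ uncorrected always holds). `fdr_correct()` wraps
Benjamini–Hochberg. `decode_performance()` predicts miniblock task success
(1 if more than half the trials were correct) from per-block estimates with
*intercept-free* logistic regression — removing the intercept centers
predictions at 0.5 under class imbalance — scored by leave-one-block-out
cross-validation, with a warning when imbalance exceeds 4:1.

## Numerical choices and edge cases

- Fisher z of a Spearman rho of ±1 is infinite: |rho| is clipped at
  $1 - 10^{-7}$ before `atanh`, keeping noiseless cases finite without
  affecting continuous data.
- Spearman ties use average ranks; demeaned continuous betas make ties
  measure-zero.
- Blocks whose pattern is constant after demeaning (rank correlation
  undefined) are excluded pairwise from both the match and mismatch means,
  with a warning count (`n_degenerate`).
- Unbalanced condition counts cycle smaller conditions through the folds so
  every block is evaluated at least once; prototypes always average the
  same number of blocks within a fold.
- A permutation-label caveat the tests encode explicitly: with strong
  condition signal present, label shuffling is not an exact exchangeable
  null for the information estimate (a small positive bias remains); exact
  centering at zero holds under the true null of unstructured patterns,
  which is what the calibration tests use.
- Divergent integrations abort naming the first non-finite step; degenerate
  designs (overlapping blocks, rank-deficient regressors, single-network
  partitions, missing labels) are hard errors with the offending entity
  named.

## Problem sizes

The shipped validation experiment uses the full study scale: 30 subjects,
250 nodes, 600 s rest and 2560 s task per subject at 10 ms resolution, 1000
sign-flip permutations. On one CPU this takes on the order of ten minutes;
unit tests run on reduced topologies (tens of nodes, tens of seconds) that
exercise identical code paths.

## Known limitations

- The transfer estimator is linear by construction; nonlinear
  inter-regional transformations are out of scope.
- No regularized FC variants (ridge/lasso) and no task-state FC.
- No Pearson-correlation transfer pipeline; `pearson_fc()` exists only as a
  diagnostic export.
- The convolutional HRF is a forward model only — no balloon/state-space
  hemodynamics, and no HRF variability across nodes.
- Empirical-scale vertex analyses (tens of thousands of vertices, geodesic
  exclusion masks from surface geometry) are supported through
  `pcreg_fc()`'s mask argument but the geometry itself must be supplied by
  the user.
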