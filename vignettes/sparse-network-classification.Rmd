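---
title: "Sparse network-based classification: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse network-based classification: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Given regional brain time-series for two balanced groups of subjects
(patients coded +1 and controls −1), `sparseFC` asks two questions: can the
groups be told apart from their functional connectivity, and if so, *which
connections* carry the discrimination? Both answers are required to be
sparse and stable: a clinically interpretable result is a short list of
region pairs that reappears when the model is refit on slightly different
subsets of subjects.

## Model

### Connectivity features

Each subject contributes an `n_t × n_p` matrix of confound-removed regional
time-series. From its sample covariance Σ we form one of four feature
matrices:

* **Correlation** Φ — pairwise Pearson coefficients;
* **Full inverse covariance** Π = Σ⁻¹ — only defined when `n_p < n_t`;
* **Partial correlation** Θ with Θᵢⱼ = −Πᵢⱼ/√(Πᵢᵢ Πⱼⱼ) — conditional
  dependence given all other regions;
* **Sparse inverse covariance** Ω — the Gaussian-graphical-model estimate,
  the penalized maximum-likelihood problem

  maximize  log det Ω − tr(ΩΣ) − λ‖Ω‖₁,

  where ‖Ω‖₁ sums the absolute values of *all* entries (including the
  diagonal) and λ ≥ 0 controls sparsity. A zero off-diagonal entry of Ω
  means the two regions are conditionally independent given the rest. We
  solve this by block coordinate descent over columns, each step a lasso
  regression against the current working covariance; zeros come out of the
  soft-threshold exactly, and no post-hoc thresholding is applied. The
  solver is validated in the test suite against an independent ADMM solver
  and against closed forms (λ = 0 recovers Σ⁻¹; a 2×2 problem with
  |σ₁₂| ≤ λ yields a diagonal Ω with entries 1/(σᵢᵢ + λ)).

The lower triangle of the chosen matrix (diagonal excluded, column-major
order, `q = n_p(n_p−1)/2` entries) is the subject's feature vector.

### Classifier

The primary classifier is a linear **L1-norm SVM with squared hinge loss**
and no intercept:

  minimize  ‖w‖₁ + C Σᵢ max(0, 1 − yᵢ wᵀxᵢ)²,

predicting sign(wᵀx). The L1 penalty zeroes most weights, so the model
itself selects discriminative connections. A dense **L2-norm hinge SVM**
(also bias-free) is available for comparison. Both solvers are compiled:
accelerated proximal gradient (FISTA with adaptive restart, exact zeros
from the proximal step) for L1, dual coordinate descent for L2, each
checked in the tests against independent convex oracles (a smooth
split-variable L-BFGS-B reformulation, and the dual KKT conditions plus
LIBSVM on bias-free symmetrized data, respectively).

### Nested cross-validation and joint accuracy/stability selection

Generalization is estimated by outer **leave-one-subject-per-group-out
(LOSGO)** folds: each of the `n_s` folds holds out one patient and one
control. Hyperparameters are chosen inside each outer fold by an inner
LOSGO loop over the remaining `n_s − 1` pairs, so the held-out pair never
influences selection.

* **λ** (sparse features only) is chosen by BIC: per inner fold and per
  group, the retained subjects' series are concatenated in time, Ω is
  fitted per candidate λ ∈ {0.1, 0.01, 0.001}, and
  BIC = −2[log det Ω − tr(ΩΣ)] + d·log(n_t) is recorded with
  d = m(m−1)/2 and m the number of distinct nonzero entries of Ω (lower
  triangle plus diagonal; a flag counts both symmetric copies instead —
  the convention is ambiguous and the package documents its choice). Each
  group's winner is the modal λ across folds; the pooled λ is the mean of
  the two winners snapped to the nearest grid value in log space (the
  grid is log-spaced), ties toward the larger (sparser) λ, because a
  non-grid λ would not be reportable against the grid. The pooled λ is then used to fit each subject's Ω from that
  subject's covariance alone.
* **C** is chosen to jointly optimize accuracy and *stability*. The
  support of a fitted model is I = {i : wᵢ ≠ 0} (for L2 models, a
  pseudo-support after trimming the smallest weights holding 1% of the L1
  mass). The chance-corrected overlap of two supports is
  O = (|Iₐ∩Iᵦ| − E)/max(|Iₐ|,|Iᵦ|) with E = |Iₐ||Iᵦ|/q, and stability Ō
  is its average over all inner-fold pairs. For every C on the grid
  (default 10⁻⁵…10⁵ in decades) each inner fold records its held-out
  accuracy; the fold's preferred C minimizes
  D = √((1−Acc)² + (1−Ō)²), and the modal preference across folds wins
  (ties toward smaller, sparser C). A flag switches to
  aggregate-accuracy-then-argmin, since the order of aggregation is a
  genuinely open choice; the default mode-of-argmins keeps each fold's
  vote intact.

The model is retrained on the whole outer training set at (λ, C) and the
held-out pair is predicted. Pooled predictions over all folds give
accuracy, sensitivity (patients correctly classified) and specificity
(controls), reported in percent, plus the mean ± sd of per-fold sparsity
and of the outer-level pairwise overlaps.

### Inference

* **Accuracy**: labels are shuffled uniformly over subjects (a shuffled
  balanced label vector stays balanced) and the entire nested CV is rerun
  per permutation; p = max(1/n_perm, n_ge/n_perm) counts permutations with
  accuracy ≥ observed. Permutation *i* is seeded `seed + i` for replay.
* **Edge weights**: the final model is refit on all subjects at the median
  per-fold parameters (median C snapped down to the grid, median λ snapped
  up — both toward sparser fits). Each permutation reruns nested CV *and*
  refit, giving a null for every edge weight; two-sided p-values compare
  |w| (discriminative relevance is sign-agnostic, and the sidedness is a
  package choice), and Benjamini–Hochberg over all q edges at q = 0.05
  marks the significant edges. Unlike the accuracy p-value, the per-edge
  p-values are *not* floored at 1/n_perm by default: an edge whose
  observed magnitude beats every permuted refit gets p = 0. With the floor
  in place the smallest attainable BH-adjusted value over q tests is
  (1/n_perm)·q/|support|, which exceeds any usable FDR level at feasible
  permutation counts — flooring would make edge-level significance
  structurally impossible, so the floor is opt-in (`floor_p = TRUE`). Per-region degrees over the significant
  edges rank the discriminative hubs. An observed weight of exactly zero
  has p = 1 by construction, so significant edges are always a subset of
  the refit support.

## Preprocessing

Regional means may be taken from a 4-D image and an integer parcellation.
Each subject's series is residualized in two sequential steps (matching
the stated processing order, rather than one joint projection): first the
six realignment parameters plus an always-included intercept — covariance
estimation needs a mean convention, so demeaning is not optional — then a
discrete-cosine high-pass basis with cutoff period 128 s. The basis size
is K = floor(2·n_t·TR/cutoff): 5 for 180 scans at TR 2 s, 8 for 256
scans. Because a fixed basis size of five is sometimes quoted for both
geometries, `dct_k` can override K. The global signal and task regressors
are deliberately left in the data. Both projections are idempotent
(residual-forming matrices), so re-cleaning a cleaned series is a no-op.

## Synthetic data: what it emulates and what it does not

The generator plants a known group difference in precision space:

* a base sparse precision template (support uniform over pairs, nonzero
  magnitudes 0.2–0.4 with random sign, diagonal = 1 + row absolute sum so
  the matrix is strictly diagonally dominant, hence PD);
* a patient template differing on exactly `n_diff_edges` pairs, changed by
  ±`effect`, planted by default on empty edges of the base so the groups
  differ in network structure, not just edge strength;
* per-subject jitter (sd `subject_noise` on nonzero entries, PD restored
  by minimal diagonal inflation with the smallest eigenvalue floored at
  0.05, which keeps the implied covariance on a usable scale) and i.i.d.
  Gaussian sampling of `n_t` time-points from the inverted precision.

Defaults mirror a balanced event-related study geometry — 19 subjects per
group, 180 time-points at TR 2 s — on a reduced 20-region parcellation
(q = 190 edges) with 5 planted differing edges. The default effect (0.25)
and subject jitter (sd 0.10) were calibrated once, jointly, against the
base magnitude range (0.2–0.4) so that each planted edge is *individually
imperfect* but *jointly decisive*: at this operating point the graphical
LASSO recovers a planted patient edge in roughly half to nine-tenths of
subjects (rather than all of them), which forces the L1 classifier to
spread weight over the whole planted set instead of picking one
representative of an interchangeable group — the regime in which support
recovery is meaningful to measure. A much larger effect paradoxically
*hurts* support recovery: every planted feature then separates the groups
on its own, the lasso keeps one and drops the rest, and permuted refits
concentrate large null weights on the same few features. The calibration
was fixed before freezing the reference experiments and is deliberately
not adjusted per run. Gaussian i.i.d. sampling matches the likelihood
the estimators assume; real BOLD data are autocorrelated, drift, and
co-vary with motion, so the generator offers AR(1) innovations
(`ar_phi`), cosine drifts and motion-correlated components to stress-test
those mismatches. It does not model hemodynamics, realistic noise
spectra, or atlas geometry — passing tests demonstrate the estimation
machinery, not fMRI realism.

## Numerical choices

* Covariance uses the 1/n_t maximum-likelihood denominator so the
  penalized likelihood is exact; `unbiased = TRUE` switches to 1/(n_t−1).
* Graphical LASSO: tolerance 10⁻⁴ on the mean absolute change of the
  working covariance per sweep (scaled by the mean |off-diagonal| of Σ),
  at most 100 sweeps, inner lasso tolerance 10⁻⁷. Supports are exact
  solver zeros. The two column-wise estimates of each symmetric entry are
  averaged; an entry is zero only when both agree on zero.
* In the overlap formula, the expected intersection is computed on the
  count scale, E = |Iₐ||Iᵦ|/q (the hypergeometric expectation); the
  printed form S(s)S(s′)/q is dimensionally consistent only when S
  denotes counts, and the two coincide there.
* L1-SVM support threshold ε = 10⁻⁸ guards float noise only; sign(0) is
  defined as +1 so predictions are total. No intercept is fitted (a flag
  exists for standardization, fitted on training folds only; both default
  off as the reference configuration).
* Empty supports: the overlap of two empty supports is 0 (with a
  warning), of one empty support 0.
* All tie-breaks point toward sparser models: smaller C, larger λ.

## Problem sizes used by the test suite

The suite validates the solvers on closed forms and random 5×5/20×50
instances against independent oracles, and the full pipeline on the
default 19+19-subject, 20-region, 180-time-point generator at the
calibrated effect (nested CV, then 50-permutation accuracy and weight
tests at a reduced C grid of 0.1/1/10, chosen so the whole suite stays
desk-scale). The null calibration repeats a 10-region, 10+10-subject,
effect-0 generator over ten seeds with 50 permutations each. These sizes
are the
package's reference experiments; larger studies simply scale the same
code.

The weight-level permutation test deserves a caveat of its own: because
the permuted refits may select a different cost C than the observed refit
(rescaling the whole weight vector without changing any prediction), the
null comparison is made on unit-L2-normalized weight vectors by default
(`normalize = FALSE` restores the raw comparison). Even so, edge-level
significance after FDR correction effectively requires an observed edge
weight that beats *every* permuted refit, and on low-dimensional problems
(tens to a few hundred edges) the planted or disease-related edges are
also the highest-variance features, which label-permuted refits recruit
when fitting noise. Edge-level permutation significance is therefore
intrinsically easier at high dimensionality, where a null refit spreads
its support over thousands of candidate edges and rarely lands on any
specific one — a point to keep in mind when interpreting the reference
experiments, which run at reduced dimensionality.

## Known limitations

* The i.i.d. Gaussian sampling model understates the effective
  autocorrelation of real BOLD series; BIC's `log(n_t)` then overstates
  the effective sample size.
* LOSGO pairing (which patient leaves with which control) is by sorted
  within-group position — any fixed pairing is equally valid, but results
  can differ slightly between pairings.
* With q ≫ n the L1-SVM solution is not unique among strongly correlated
  features; stability-aware selection of C mitigates, but does not
  remove, the arbitrariness of which of two collinear edges is picked.
* Permutation tests rerun the entire framework and dominate runtime;
  `n_perm = 100` at the default grids is an overnight-scale computation
  for large q, which is why the reference experiments use reduced grids.
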