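---
title: "Methods: integrated interface prediction with ispip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated interface prediction with ispip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ispip)
```

## The problem and the model

A protein's interface residues — those with at least one heavy atom within
4.0 Å of a binding partner in the complex — are a small minority of its
residues, and the structure-based methods that predict them draw on
different information sources: structural-neighbour templates,
intrinsic features, or the geometry of many docked poses. Their errors are
therefore only weakly correlated, and a meta-classifier trained on their
per-residue scores $x_1,\dots,x_k \in [0,1]$ can beat each of them.

`ispip` fits four such integrators. The regressions are

$$P(i \mid x) = \frac{1}{1 + e^{-(b_0 + \sum_j b_j x_j)}}
  \qquad\text{(logistic, maximum likelihood)}$$

$$I(x) = b_0 + \sum_j b_j x_j
  \qquad\text{(linear, ordinary least squares, clipped to } [0,1])$$

The tree ensembles are a random forest (bootstrap-aggregated CART
probability trees; the prediction is the mean terminal-node interface
fraction) and gradient-boosted trees (histogram-based boosting where each
tree fits the loss gradient of the ensemble so far). All four emit a
per-residue interface likelihood in $[0,1]$.

Binary calls use a *dynamic cutoff*: for a protein with $R$
surface-exposed residues, the $N$ top-scoring residues are called
interfacial with

$$N = 6.1\,R^{0.3}.$$

Model assumptions worth keeping in mind: scores are comparable across
proteins (they are normalized to $[0,1]$ upstream or via
`normalize_scores()`); the label is a deterministic function of the
complex structure used for annotation; and proteins are exchangeable —
the grouped cross-validation and the unweighted per-protein averages both
treat the protein, not the residue, as the sampling unit.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| contact cutoff | 4.0 | Å | heavy-atom convention for interface annotation; also used for per-pose interfaces |
| SASA probe radius | 1.4 | Å | water-sized rolling probe |
| surface threshold | 0.05 | relative SASA | residues at ≥ 5% of their residue-type maximum count toward $R$ |
| forest | 100 trees, depth 10, α = 0 | — | the optimized configuration for three input channels |
| boosting grid | loss ∈ {log-loss, squared}, η ∈ {0.05, 0.1, 0.3}, rounds ∈ {50, 100, 200}, depth ∈ {3, 6} | — | default CV grid; single fits default to log-loss, η = 0.1, 100 rounds, depth 3 |
| CV folds | 5 | proteins | grouped by protein; objective is mean per-protein F under the dynamic cutoff |
| docking partners × poses | 13 × 2000 | — | canonical pose budget; any counts are accepted |

All randomized steps (fold assignment, bootstrap resamples, simulation)
take an explicit seed and derive named substreams from it, so a master
seed reproduces a run byte-identically.

## Numerical and convention choices

- **Rounding of $N$**: the power law is not integer-valued and its source
  does not fix a rounding rule. We round half-up (`floor(x + 0.5)`), with
  `floor`/`ceiling` available; $N$ is floored at 1. Half-up keeps
  $N(1) = 6$, matching the intuition that even the smallest protein gets
  a handful of calls.
- **Ties at rank $N$**: broken by table order (first listed wins), making
  `classify_top_n()` deterministic; exactly $\min(N, n)$ residues are
  always called positive.
- **Zero denominators**: precision, recall, F and MCC are defined 0 and
  flagged (`degenerate`) when their denominator vanishes, so unweighted
  means over proteins are always defined. Degenerate proteins are counted
  and reported rather than silently dropped.
- **Curves**: thresholds sweep the distinct score values from high to
  low; both AUCs are plain trapezoids over the stored points. With this
  construction the pooled ROC-AUC equals the Mann–Whitney statistic
  $U/(n_+ n_-)$ with ties counted half — the identity the test suite
  asserts to $10^{-10}$. The PR curve is prepended with
  (recall 0, first-point precision) and nothing else is interpolated.
  Curves pool residues across proteins by default; `per_protein_auc()`
  provides the macro-averaged alternative, since either convention is
  defensible and the field uses both.
- **Perfect separation**: the logistic fit detects non-convergence or
  exploding coefficients and refits with a small L2 ridge
  (λ = 10⁻⁴), keeping coefficients finite while preserving the score
  ordering. Rank-deficient linear designs likewise fall back to a tiny
  ridge.
- **Linear predictions** are clipped to $[0,1]$; the linear likelihood is
  only meaningful inside the unit interval and out-of-range handling is
  otherwise unspecified.
- **SASA**: Shrake–Rupley point sampling with a deterministic Fibonacci
  sphere lattice (92 points/atom by default; the two-sphere closed form
  is reproduced to ~1%). Relative accessibility divides by
  Tien-style theoretical maxima and is clipped to $[0,1]$; non-standard
  residues fall back to the glycine maximum. Hydrogens are excluded from
  both SASA and contact detection, as most depositions lack them.
- **Interface annotation** is the pure heavy-atom distance criterion. A
  stricter contact-legitimacy scheme (e.g. occlusion-based filtering) can
  be plugged in through the `contact_filter` hook; the distance term
  dominates in practice and reimplementing a full contact-classification
  algorithm is out of scope.
- **Residue identity** is the verbatim (chain, residue number, insertion
  code) triple from the coordinate file; no renumbering. Alternate
  locations resolve to the highest-occupancy conformer.

## Open design decisions

- *What does cross-validation "optimize" for closed-form regressions?*
  OLS and the logistic MLE determine their coefficients exactly, so a CV
  that "selects parameters by held-out F" is ambiguous. Both readings are
  implemented: `regression_final = "best_fold"` returns the fold-fitted
  candidate coefficient vector with the highest held-out F (selection as
  worded), `"refit_all"` (default) refits on all training proteins (the
  statistically conventional choice; with 4/5 overlap between folds the
  candidates differ little).
- *Random-forest engine.* The forest is built as bootstrap-aggregated
  `rpart` probability trees rather than through a dedicated RF package
  because the configuration includes a cost-complexity pruning parameter
  α, which `rpart::prune()` exposes directly and the installed RF engines
  do not. With only three predictor channels, per-node feature
  subsampling contributes little; a per-tree `mtry` option is provided.
- *Docking-score pooling.* Whether the pose-frequency score averages
  per-partner fractions or pools all poses is unspecified in its source;
  the two coincide at equal pose counts. Equal partner weighting is the
  default, pooling is behind `pooled = TRUE`.
- *Bound or unbound $R$, and the exposure threshold*: both are
  configuration options (`context`, `threshold` in
  `surface_residues()`), documented defaults unbound-chain and 5%.

## What the synthetic generator emulates — and what it does not

`simulate_scores()` reproduces the *statistical* structure the integrator
relies on: protein lengths uniform on 50–450 residues, a per-protein
interfacial fraction that is Beta-distributed with mean 0.12, and score
channels drawn from label-conditional Beta distributions
(Beta(4, 2) for interfacial vs Beta(2, 4) for non-interfacial at the
"moderate" default) coupled through a Gaussian-copula latent factor with
correlation ρ. ρ = 0 models orthogonal predictors; driving ρ toward 1
collapses them to redundancy, and integration gains shrink accordingly —
a property of the generator used in testing, not an empirical claim about
any real predictor set. Channel failure (a predictor silently carrying no
signal for some proteins, as happens when a template-based method finds
no structural neighbours) is modeled by scoring against a relabelling of
the protein's residues, which preserves the marginal score distribution
while destroying its information content.

What it deliberately does not emulate: real geometry (surface counts are
set to 70% of length rather than computed), docking energetics, sequence
redundancy between proteins, and any systematic miscalibration or
correlation structure of real upstream predictors beyond the single
shared factor. Passing tests on this generator therefore demonstrate the
correctness and the qualitative behaviour of the integration machinery —
gains over the best input, robustness to channel failure — not the
quantitative performance to expect on a real benchmark, which depends on
the real predictors' error structure.

Toy structures follow the same philosophy: `generate_toy_complex()`
places C-α pseudo-atoms so that designated interface residues sit 3.4 Å
from a partner atom and all others beyond 6 Å, bracketing the 4.0 Å rule
with safe margins; `generate_pose_fixture()` emits pose sets whose
empirical interface frequencies match a prescribed schedule exactly.

## Problem sizes

The shipped tests and the acceptance script use 130 simulated proteins
(100 training + 30 test, ~32,000 residues) for the end-to-end benchmark,
10 simulation seeds for the integration-gain and robustness properties,
$n = 2\times 10^4$ for logistic parameter recovery, and 100 random
score/label sets up to $n = 10^4$ for the AUC identity. These sizes give
stable estimates for every property checked while keeping a full run in
the minutes range.

## Known limitations

- The SASA implementation is pure R and intended for the package's
  annotation and counting purposes, not for high-throughput surface-area
  pipelines.
- The bootstrap AUC-difference test resamples proteins and reports a
  sign-reversal p-value; it is a pragmatic comparison, not an exact
  variance estimator (no DeLong-style covariance).
- One-sample KS with estimated mean and sd is conservative; use
  `lilliefors = TRUE` when normality of a sample with unknown parameters
  is the actual question.
- mmCIF input, biological-assembly generation and structure quality
  checks are out of scope; PDB parsing covers ATOM/HETATM records with
  altloc and insertion-code handling.
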