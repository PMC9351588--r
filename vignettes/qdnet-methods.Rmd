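---
title: "Quasi-dynamic network inference from cross-sectional abundance data: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-dynamic network inference: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdnet)
```

## The problem

Microbiome surveys are usually cross-sectional: many habitats (gut
positions, subjects, sites) measured once. Interaction inference normally
needs dynamics. `qdnet` substitutes the **habitat index** — the summed
abundance of all taxa in a sample, a measure of how much life the habitat
carries — for time. Samples ordered by habitat index trace out a
quasi-dynamic axis along which each taxon's abundance can be modelled,
decomposed, and attributed to other taxa.

This vignette explains each model layer, the assumptions it rests on, the
tunable parameters, what the synthetic-data generator does and does not
emulate, and the design decisions taken where the methodology was
genuinely open. It states no empirical result that the package's test
suite and acceptance script do not themselves compute.

## 1. Allometric scaling

Each taxon's abundance (niche index) is tied to the habitat index by a
power law, `y_j = α_j H^β_j`. The default fit is ordinary least squares of
`log y` on `log H` over the positive observations (closed form,
scale-equivariant); `method = "nls"` refines it on the original scale.
Both R² conventions are reported because they answer different questions:
the log-scale R² describes fit across the full dynamic range, the
original-scale R² is dominated by the most abundant samples. Zeros are
dropped rather than pseudocounted by default (`pseudocount` is available);
a fit requires at least three positive observations.

The fitted curve `ŷ_j(H)` is the taxon's *smoothed state*: it converts
the static table into the quasi-dynamic representation used by all later
stages.

## 2. Why estimation lives on the log scale

Abundances span orders of magnitude and their noise is multiplicative. Two
consequences drive the package's numerical design:

* a bounded polynomial basis (Legendre polynomials on [−1, 1]) cannot
  represent responses spanning decades on the original scale, so the
  partner-selection regression operates on **log abundance**, where power
  laws are straight lines, lognormal noise is homoscedastic, and the
  basis is well conditioned;
* all basis arguments are **log-transformed** before the affine map onto
  [−1, 1]; otherwise the heavy upper tail of an abundance distribution
  squashes most samples into a corner of the basis domain.

## 3. Partner selection

For focal taxon *j*, the log abundance is regressed on one Legendre block
(order `r`, default 3) per potential partner, the block's argument being
the partner's observed abundance, plus an unpenalized block in the
focal's own smoothed curve that represents the independent term `a_j(W)`.
Two structural choices matter:

* **Observed, not smoothed, partner predictors.** Smoothed power curves of
  different taxa are near-collinear over a modest habitat range (any
  smooth monotone curve is approximated by a low-order polynomial family
  in any other), so smoothed predictors carry no attributable signal.
  What identifies a partner is its *individual variation* around its own
  curve, which only the observed values carry. `predictor = "smoothed"`
  remains available for genuinely smooth (e.g. noise-free) data.
* **A flexible independent block.** The focal's own block receives two
  extra polynomial degrees: anything expressible as a smooth function of
  the habitat axis belongs to the independent component; if the
  unpenalized block cannot absorb such curvature, partner blocks soak it
  up as spurious links.

Selection is two-stage: a group LASSO over a 50-point log-spaced penalty
grid (down to `1e-5 λ_max`; entry thresholds span decades on the log
scale), then an adaptive group LASSO whose per-group weights are the
reciprocals of each group's largest norm along the stage-1 path. Stage 1
thus acts as a *screener* — only groups that never enter the path are
excluded outright (`w = ∞`). Each visited support is scored by BIC on its
**debiased** (refitted) residual sum of squares with `df` equal to the
parameter count; scoring the shrunk path solutions instead would bias the
choice toward over-sparsity. The prescribed weight function
`z(W) = (W − W_1)(W_n − W)` (normalized, zero at the boundaries) is the
simplest polynomial satisfying the stated boundary conditions; an
unweighted option exists and is the default wherever a likelihood
interpretation is needed (see §6). The block-coordinate solver performs
exact per-block minimization in the eigenbasis of each block's weighted
Gram matrix (compiled code), declaring convergence on the objective.

## 4. The quasi-dynamic ODE decomposition

With links fixed, taxon *j*'s abundance is written as the sum of an
independent trajectory and one dependent trajectory per partner, each the
RK4 integral of its own derivative function:

* `dG_j/dH = (ŷ_j(H)/H) · Σ_k θ_k P_k(u_j(H))`,
* `dG_jj′/dH = (ŷ_j(H)/H) · Σ_k θ_k P_k(u_j′(H))`,

with `u` the log-mapped argument curves. The **allometric prefactor**
`ŷ_j/H` makes a pure power law correspond to a constant derivative
function (`dy/dH = β y/H`), so trajectories track the focal's dynamic
range with low polynomial order. At the smallest habitat index the
observed abundance is assigned wholly to the independent component and
every dependent component starts at zero — the minimal convention making
the decomposition identifiable at the boundary.

**Estimation is two-step, and this is deliberate.** The integral design
alone is degenerate: all its columns are smooth functions of *H*, so a
joint least-squares fit splits the signal among components arbitrarily.
Worse, integration averages away the pointwise partner-specific variation
that identifies attribution. The package therefore first fits the
*pointwise* log-scale regression (the selection-stage model, with the
partner blocks orthogonalized against the focal's own block so that all
habitat-driven structure is attributed to the independent component), and
then projects each pointwise component target onto its own Q-integral
block by ridge-stabilized weighted least squares. Additivity
(`fitted = independent + Σ dependent`) holds to machine precision, each
trajectory is exactly the RK4 integral of its own Q series, and the
attribution inherits the identifiable pointwise estimates.

**Edge signs are response slopes.** For a fluctuation-driven interaction
the *mean* of a dependent component is sign-ambiguous in principle (a
mean-zero log-scale influence still produces a non-negative mean effect on
the original scale). What is identifiable — and what "promotion" or
"inhibition" means — is the direction of the fitted response of the focal
to the partner. Network edges therefore carry magnitude equal to the
aggregated |dependent component| and sign equal to the sign of the mean
fitted response slope.

## 5. Networks, interaction types, roles

Edges below the neutrality threshold ε (default 5% of the target taxon's
mean abundance — the methodology needs *some* numeric notion of
"neutral", and relative-to-abundance is the scale-free choice) keep sign
0: they participate in pair classification but not in role degrees. The
3 × 3 table of thresholded sign pairs maps exhaustively onto seven
ecological labels (mutualism, antagonism, commensalism, amensalism,
parasitism, altruism, neutral). Roles use the thresholded graph: a
*leader* has more outgoing than incoming links, a *hub/keystone* more
outgoing links than the mean total connectivity, a *solitary* taxon fewer
total links than the mean (strict inequalities, so an edgeless network
has no solitary nodes). Restricting the evaluation samples to one
position, subject, or single sample yields position-specific or
personalized (instantaneous) networks; the edge *support* always comes
from selection and does not change with the evaluation subset.

## 6. Context comparison

Whether network structure differs among C contexts is tested by a
likelihood ratio: the null model is one pooled fit; the alternative
refits the ODE-stage coefficients per context on the *shared* link
support selected from pooled data (the model class that varies across
contexts is the coefficient set, not the support — this also keeps the
permutation exchangeable). Fits here use uniform weights, so weighted
least squares coincides with the Gaussian MLE and the alternative
properly nests the null; likelihoods are evaluated under the independence
working model (diagonal residual covariance), because the full
block-covariance MLE is near-singular at per-context sample sizes
comparable to the taxon count and would let covariance overfit dominate
the statistic. The full block covariance (per-taxon variances plus
pairwise residual covariances) remains available through
`residual_covariance()`/`qdode_loglik()` for reporting. Significance
comes from a permutation null: labels reshuffled with group sizes
preserved, the 95th nearest-rank percentile as the critical threshold,
and an add-one p-value. The reference protocol uses 1000 permutations;
the package's own calibration studies use 200 with 100 replicates.

## 7. The synthetic-data generator

`generate_abundance()` emulates: power-law baselines with exponents
spanning a realistic range (most taxa increasing with habitat index, a
minority decreasing); habitat indices log-uniform over two decades; a
planted sparse signed network; module structure (tight per-module curve
families); lognormal noise (default `sigma_log = 0.2`); and optional
context effects (sign flips or strength multipliers on chosen edges).

Planted interactions are *power laws themselves*: an edge of strength *s*
shifts the focal's log abundance by *s* standard deviations of the
partner's log abundance. This is the log-linear (multiplicative
Lotka–Volterra) form — strictly positive abundances at any strength, and
exactly representable by the estimation bases. The community is assembled
sequentially in random order, so the planted network is a DAG and every
focal responds to its partners' *final realized* abundances — the same
quantities the inference observes. (A cyclic generative system requires a
fixed point that diverges at meaningful interaction strengths, and
coupling to pre-interaction abundances makes the observed partner a
mostly-error proxy of the generative covariate.)

What the generator does **not** emulate: compositionality or sequencing
depth artifacts, zero inflation, phylogenetic correlation between taxa,
feedback loops (the planted graph is acyclic), and the circularity
between habitat index and abundances (the drawn H and the realized row
sums differ; the truth bundle records the discrepancy). Passing tests
therefore show that the machinery recovers what it models — not that real
16S data meet these assumptions.

A hard limit worth stating plainly: in cross-sectional data, every smooth
(habitat-driven) part of a dependent component is absorbed by the focal's
own independent term, so link recovery rides entirely on the
partner-specific variation channel, whose effective signal-to-noise is
bounded by the interaction strength regardless of measurement noise. The
package's validation studies show near-perfect *sign* recovery on
recovered links, but support-recovery F1 far below what the same
machinery would achieve on genuinely dynamic data. Single-link planted
problems are recovered reliably; dense planted networks (several partners
per focal among many similar decoys) are not fully recoverable by any
estimator under these conditions — an intrinsic property of the
cross-sectional design, not of the implementation.

## 8. Numerical choices and defaults

| Parameter | Default | Why |
|---|---|---|
| LOP order `r` | 3 | small sample sizes in motivating designs (~23 samples); the independent block gets `r + 2` |
| λ grid | 50 points, `λ_max` to `1e-5 λ_max` | group entry thresholds span decades on the log scale |
| Selection criterion | BIC on debiased refits | comparable to exhaustive subset scoring |
| ε (neutrality) | 0.05 × target's mean abundance | scale-free; configurable |
| RK4 substeps | 8 per grid interval | step-halving changes trajectories < 1e−6 (smooth arguments) |
| Duplicate H | perturbed by 1e−12 × range | the ODE needs a strictly increasing axis |
| EM (clustering) | lognormal mixture, closed-form M-step | original-scale Gaussian mixtures split steep modules spuriously; the log-scale M-step is a weighted linear regression, so the EM is exactly monotone |
| Module count | BIC, penalty `(4L−1) log(nm)` | 4 parameters per module, one constraint on the proportions |
| `n_perm` | 1000 (package default) | reference protocol; calibration studies use 200 |

Degenerate inputs: zero-total samples are dropped with a warning (the
habitat index must be positive); constant partner curves collapse to
intercept-only blocks and are flagged; empty mixture components trigger a
restart; variances are floored at 1e−8 × the data variance.

## 9. Problem sizes used in the validation studies

The bundled studies run at desk scale: allometry recovery at n = 50
samples × 20 taxa; link/sign recovery at m = 20 taxa, n = 60 samples, 3
planted partners per focal, 20 replicates; best-subset agreement on
6-partner problems, 20 replicates; module recovery at 30 taxa in 3
modules, 20 replicates; permutation calibration at 200 permutations × 100
replicates; and an end-to-end determinism check on a 23 × 17 scenario
mirroring a phylum-level gut survey. These sizes were chosen to make the
full suite a routine desk run while keeping every study large enough for
its acceptance band to be meaningful.
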