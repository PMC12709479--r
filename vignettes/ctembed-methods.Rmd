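---
title: "Methods: cell-type-aware embeddings and symmetry discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type-aware embeddings and symmetry discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctembed)
```

## Motivation

Connectomes are weighted directed graphs, but many neural circuits are not
"just graphs": head-direction systems live on a ring, grid-cell modules on a
torus, visual projections on a retinotopic sheet, and some reciprocal
pathways connect corresponding positions with a systematic angular offset.
`ctembed` makes these continuous structures recoverable from connectivity
alone by (a) embedding neurons in a low-dimensional latent space under a
probabilistic edge model, and (b) providing explicit statistical machinery to
ask whether the embedded geometry matches a hypothesized symmetry.

A central design decision is that cell types are first-class. Connection
statistics differ wildly across type pairs (an inhibitory block and an
excitatory block with the same latent geometry have very different gains and
baselines), and a single global weight-distance relationship would force the
latent space to absorb those differences. `ctembed` therefore learns separate
gain, baseline, and length-scale parameters for every ordered pair of types,
letting the latent positions encode geometry only.

## The edge model

For neurons $i, j$ with types $m = c_i$, $n = c_j$ and latent positions
$Z_i, Z_j \in \mathbb{R}^D$:

$$
\hat W_{ij} = \mathrm{softplus}\!\left(
  A_{mn} \exp\!\left(-\frac{d(Z_i, Z_j)^2}{C_{mn}^2}\right) + B_{mn}
\right),
$$

with $d(Z_i,Z_j) = \lVert Z_i - Z_j\rVert$ by default. The softplus keeps
means positive while permitting effectively-zero baselines; the length scale
is parameterized as $C = 10^{-3} + \mathrm{softplus}(C_\text{raw})$ so it can
never collapse.

Two likelihoods are available. For synapse counts, Poisson:
$\ell_{ij} = \hat W_{ij} - W_{ij}\log\hat W_{ij} + \log\Gamma(W_{ij}+1)$.
For continuous strengths, Gaussian with mean-dependent variance
$v_{ij} = 1 + \hat W_{ij}^2$, which mimics the multiplicative noise of real
weight estimates. The training objective adds a ridge term
$\lambda (ND)^{-1} \lVert Z\rVert^2$ with $\lambda = 0.1$, which fixes the
scale gauge of the latent space (the model is otherwise invariant to jointly
rescaling $Z$ and $C$).

### Rotations for phase shifts

With `rotations = TRUE` the distance becomes
$d = \lVert Z_i - R_{mn} Z_j \rVert$ where each $R_{mn} = \exp(G_{mn})$ is a
rotation generated by a learned skew-symmetric $G_{mn}$. If type $P$ projects
to the position on type $Q$'s ring that is $\Delta\theta$ ahead, the model
absorbs the offset into $R_{PQ}$. The *loop statistic*

$$
\frac{180}{2\pi}\,\lVert \log R_{mn} + \log R_{nm} \rVert_F
$$

(in degrees, via the principal matrix logarithm) measures how far a
reciprocal pair of rotations is from cancelling: exact inverses give 0, while
a genuine phase-shifted loop leaves a residual rotation. Angles within
numerical reach of $\pi$ are flagged because the principal log is
ill-conditioned there. `rotation_report()` tabulates the statistic for all
type pairs.

### Optimization

Training is full-batch Adam (learning rate 0.01, default 5000 steps) with
fully analytic gradients, including the adjoint (Fréchet derivative) of the
matrix exponential for the rotation generators; gradients are projected so
$G$ stays exactly skew-symmetric and $R$ exactly unitary throughout. An
optional holdout of directed pairs gives an out-of-sample negative
log-likelihood per pair, which is how we compare model variants (for
example, type-aware versus a single shared parameter set).

## Geometry matching

Given a hypothesized target geometry $T$ (unit circle with $M$ evenly spaced
points, or a Clifford torus: rows $(\cos u, \sin u, \cos v, \sin v)$ of norm
$\sqrt 2$ over a $K_1 \times K_2$ grid), we solve

$$
\min_{\Pi, P}\; \lVert T - \Pi Z P \rVert_F^2
$$

over permutations $\Pi$ and linear projections $P$ by alternating two exact
subproblems: with $P$ fixed, the optimal $\Pi$ is a linear assignment problem
(solved exactly by a C++ Jonker–Volgonant implementation); with $\Pi$ fixed,
the optimal $P$ is least squares. The report statistic is
$r^2 = 1 - \text{loss}/\lVert T\rVert^2$.

The alternation only finds a local optimum, so `match_geometry()` uses
restarts. Random restarts alone turn out to be surprisingly weak on ring
problems: the alternating map has many fixed points whose losses are nearly
flat, so even when the fitted embedding is an essentially perfect circle, a
randomly initialized alternation frequently converges to a scrambled
ordering. The first restart is therefore deterministic and data-driven: for
circle targets, the initial permutation orders neurons by their angle in the
top-two principal-component plane of $Z$; for torus targets, a single
assignment step matches the RMS-scaled top-$K$ PCA projection to the target.
Remaining restarts stay random, and the best loss wins — the objective is
unchanged, only the initialization is smarter. On synthetic rings this moved
ordering agreement from roughly 20–60% to 100% without touching the model or
the data.

`assign_angles()` pushes the learned projection $P$ onto *all* neurons,
giving every neuron an angle on the shared recovered ring; this is what makes
cross-type comparisons (phase-shift tuning curves) possible, and
`match_geometry(..., fixed_P = )` re-matches a second type under the first
type's projection to test whether two populations share one map.

## Circularity screening and its null

`circularity_coefficient()` is the matcher's $r^2$ against a circle target.
Its null distribution — the $r^2$ achieved by matching i.i.d. Gaussian point
clouds of the same size and dimension — is far from zero (the matcher is free
to pick both the ordering and the projection), so significance must be
calibrated. `circularity_null()` draws 100 independent Gaussian clouds,
matches each, and fits a Gaussian to the resulting coefficients;
`circularity_pvalue()` reports the upper-tail probability. On 50 fresh
Gaussian clouds the test is calibrated (over 90% of p-values exceed 0.05),
while both noisy circles and embeddings actually fitted to ring circuits
reject at $p < 0.01$. `screen_types()` runs this per type and returns a tidy
table.

## Phase-shift tuning curves

Independently of the rotation variant, a phase shift is visible in raw
connectivity once neurons have recovered angles: `tuning_curve()` bins the
cross-type weights $W_{ij}$ by the angular offset
$\theta_j - \theta_i$ (wrapped, on a regular grid of bin centers) and reports
the mean weight per bin plus the peak offset. On a two-type circuit generated
with a $2\pi/8$ offset, the peak of the tuning curve computed from *recovered*
angles lands within one bin of $2\pi/8$.

## Retinotopy

`receptive_field_map()` reduces per-neuron synapse clouds in a target
neuropil to centroids and projects them onto their top-two principal plane
(the recovered retinotopic sheet). `coordinate_decoding_r2()` measures how
linearly decodable an anatomical coordinate is from the embeddings; under
independence its expectation is $D/(M-1)$, which the package's tests verify
by simulation — a reminder that decoding $R^2$ values need small-$M$
skepticism. `directional_retinotopy()` profiles decodability over directions
in the sheet (0°–175° in 5° steps), distinguishing full two-dimensional maps
from one-dimensional gradients. `projection_r2()` scores how well the fitted
model reproduces a specific projection block (this can be negative when the
model does worse than a constant), and `rank_projections()` orders all
type-pair blocks by that score, excluding blocks whose mean weight is too low
to be informative.

## Synthetic circuits

Three generators provide exact ground truth:

- `make_ring_connectome()`: neurons at evenly spaced angles; block means
  $a_{mn}\exp(-\mathrm{wrap}(\theta_j - \theta_i - \Delta\theta_{mn})^2 /
  \sigma_{mn}^2) + b_{mn}$, with optional Poisson sampling. Defaults: three
  types of 16, gain 10, baseline 0.1, $\sigma = 0.8$, a reciprocal
  $\pm 2\pi/8$ offset between the first two types.
- `make_grid_connectome()`: an excitatory sheet on a wrapped (toroidal)
  $n_E \times n_E$ grid with kernel $e^{-\gamma d^2} - I$, an inhibitory
  sheet coupled by $e^{-(\beta/2) d^2}$, reciprocal I→E magnitudes with
  inhibitory sign carried as metadata, and the whole matrix rescaled so its
  maximum is exactly `w_max` (default 100). The kernel widths follow a
  documented size scaling ($\lambda \propto n_E$, $\beta = 3/\lambda^2$,
  $\gamma = 1.05\beta$).
- `make_retinotopic_connectome()`: a source sheet with a square grid of
  receptive fields projecting to spatially selective targets (Gaussian in RF
  space) and unselective targets (uniform), with no back-projections.

## Known limitations

- **Gauge freedom.** The loss is invariant to orthogonal transforms of the
  latent space, so recovered rings are defined only up to rotation and
  reflection. All downstream comparisons (ordering agreement, tuning-curve
  peaks) must — and in this package do — account for that, e.g. by choosing
  the reflection that best matches a reference ordering before reading off a
  signed peak.
- **Winding degeneracy at low noise.** For a noise-free ring with
  $\sigma = 0.8$, a doubly wound helical embedding achieves nearly the same
  likelihood as the single-wound circle: the weight profile is too broad to
  pin the winding number. With realistic Poisson sampling the degeneracy
  breaks and the single winding wins, but users analyzing very smooth,
  noise-free connectivity should screen matched orderings against adjacency
  (as the torus analysis does) rather than trust $r^2$ alone.
- **Matcher locality.** Even with the PCA-seeded restart, the alternating
  matcher is a local method; for small populations (`M` up to about 7 the
  tests compare against exhaustive search) restarts suffice, but very noisy
  large populations may need more restarts.
- **Scale.** Optimization is full-batch and dense ($O(N^2 D)$ per step);
  circuits of a few thousand neurons are comfortable on one core, but the
  package is not engineered for whole-brain matrices.

## Reproducibility

Every stochastic component (generators, initialization, holdout, restarts,
nulls) takes an explicit seed, and the command-line pipeline writes a
provenance JSON next to its artifacts. The end-to-end acceptance check is
`scripts/acceptance.R`.
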