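# ctembed

Cell-type-aware graph embeddings for discovering symmetries in connectomes.

`ctembed` learns a low-dimensional latent position for every neuron in a
weighted, directed connectome while explicitly modelling cell-type-level
connectivity. When the underlying circuit has a continuous organization — a
ring attractor, a toroidal grid-cell sheet, a retinotopic map, or reciprocal
projections with a systematic phase shift — that organization shows up as
geometry in the learned embedding, and the package ships the tools to detect,
match, and quantify it.

## The model

Each neuron `i` carries a latent vector `Z_i` in `D` dimensions and a cell
type `c_i`. The expected weight of the directed edge `i → j` is

```
Ŵ_ij = softplus( A[c_i, c_j] · exp( −d(Z_i, Z_j)² / C[c_i, c_j]² ) + B[c_i, c_j] )
```

where `A`, `B`, `C` are per-type-pair gain, baseline, and length-scale
matrices, and `d` is Euclidean distance. Optionally, each ordered type pair
gets its own unitary rotation `R[c_i, c_j]` (parameterized as the matrix
exponential of a skew-symmetric generator), and the distance becomes
`‖Z_i − R[c_i,c_j] Z_j‖`; a reciprocal pair of learned rotations that fail to
cancel around the loop is direct evidence of a phase-shifted projection.

Observed weights enter through a Poisson likelihood (synapse counts) or a
Gaussian likelihood with mean-dependent variance `v = 1 + Ŵ²` (continuous
strengths). The loss is the negative log-likelihood plus a small ridge penalty
on `Z`, minimized by full-batch Adam with fully analytic gradients (including
the Fréchet derivative of the matrix exponential for the rotation variant).

Downstream analyses:

- **Geometry matching** — align a type's embedded point cloud to a canonical
  circle or Clifford-torus target by alternating an exact linear-assignment
  step (Jonker–Volgonant, in C++) with a least-squares projection, yielding a
  neuron ordering and a goodness-of-fit `r²`.
- **Circularity screening** — an `r²`-based circularity coefficient per type
  with a Gaussian-null significance test, so ring structure is a calibrated
  statistical finding rather than an eyeball judgment.
- **Phase shifts** — a rotation-report statistic (degrees of uncancelled
  rotation around each reciprocal type-pair loop) plus connectivity tuning
  curves over recovered angular offsets.
- **Retinotopy** — receptive-field maps from synapse clouds, linear decoding
  `R²` of anatomical coordinates from embeddings, directional decoding
  profiles, and a ranking of projection blocks by embedding explainability.
- **Synthetic generators** — ring circuits with per-block offsets, scaled
  excitatory/inhibitory toroidal grid sheets, and retinotopic projection
  circuits, all with exact ground truth for end-to-end validation.

## Worked example

Simulate a three-type ring circuit with Poisson synapse counts, fit a
type-aware embedding, screen every type for circularity, and recover the
ring ordering of one type:

```r
library(ctembed)

gen <- make_ring_connectome(ring_circuit_spec(seed = 501))
gen$cx
#> <connectome> 48 neurons, 3 types, 1051 nonzero edges, total weight 5056
#>   types: R1 (16), R2 (16), R3 (16)

fit <- fit_embedding(gen$cx, D = 5, config = train_config(n_steps = 2000, seed = 1))
glance(fit)
#> # A tibble: 1 × 10
#>   n_neurons n_types     D likelihood type_aware rotations n_steps_run loss_final ...
#> 1        48       3     5 poisson    TRUE       FALSE            2000      2658.

screen_types(fit, n_null = 100, seed = 42)
#> # A tibble: 3 × 5
#>   type  n_neurons    r2  p_value p_lower
#> 1 R1           16 0.989 0.000298   1.000
#> 2 R2           16 0.988 0.000329   1.000
#> 3 R3           16 0.986 0.000424   1.000

idx <- which(fit$model$types == 1L)
mt <- match_geometry(fit$model$Z[idx, , drop = FALSE], circle_target(16),
                     n_restarts = 10, seed = 1)
mt$r2
#> [1] 0.989
mt$perm   # the true ring order, up to a cyclic rotation
#> [1]  4  5  6  7  8  9 10 11 12 13 14 15 16  1  2  3
```

Phase shifts between reciprocally connected types are read off the rotation
report. Here type `P` projects to type `Q` with a 45° angular offset, and the
loop statistic for the `P`–`Q` pair stands far above the within-type values:

```r
off <- matrix(0, 2, 2); off[1, 2] <- 2 * pi / 8
gen <- make_ring_connectome(ring_circuit_spec(
  n_per_type = c(P = 16, Q = 16), offset = off, seed = 601))
fr <- fit_embedding(gen$cx, D = 2, rotations = TRUE,
                    config = train_config(n_steps = 2000, seed = 1))
round(rotation_report(fr)$stat, 2)
#>       P     Q
#> P  0.28 11.25
#> Q 11.25  0.59
```

## Command-line interface

`inst/cli/ctembed` exposes the pipeline as subcommands operating on a run
directory (`simulate-ring` / `simulate-grid` / `simulate-retino`, `embed`,
`screen`, `match`, `phase`, `retino`), exchanging Matrix-Market adjacency
files and TSV tables so stages can be rerun or inspected independently:

```sh
ctembed simulate-ring --outdir run1 --seed 5
ctembed embed --outdir run1 --D 5 --n_steps 2000
ctembed screen --outdir run1
ctembed match --outdir run1
```

## Further reading

The methods vignette (`vignettes/ctembed-methods.Rmd`) covers the model and
optimizer in detail, the geometry-matching algorithm and its initialization,
the null calibration of the circularity test, and known identifiability
limits (reflection/rotation gauge freedom and winding-number degeneracy of
ring solutions at low noise).
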