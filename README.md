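# avref

Construction of an **average-volume reference space** for multi-subject
deformable registration of whole-body volume images.

Atlas-based analysis of cohorts of whole-body images (for example fat/water
separated MR) maps every subject to a common reference space by deformable
registration and then studies quantities voxel by voxel. Local tissue
volume is carried by the Jacobian determinant of the mapping, so any
systematic volume bias of the reference space itself leaks into every
downstream correlation analysis. `avref` builds a reference that is neutral
with respect to local volume: at every voxel, the average volume change of
the mappings to the whole cohort is zero.

## The method

A deformation is f(x) = x + u(x) with Jacobian determinant J[f] =
det(∂f_i/∂x_j), the local volume-change ratio. Given fields f_1 … f_n that
register the cohort to an initial reference, a correction field d with

    J[d] = ( ∏_i J[f_i] )^(1/n)

makes the composed mappings f_i ∘ d⁻¹ satisfy ∏_i J[f_i ∘ d⁻¹] = 1
voxel-wise — zero average pointwise volume change. The package computes the
mean Jacobian under logarithm with a lower clamp ε (default 0.01) to remove
fold singularities,

    J̄ = exp( (1/n) Σ_i ln max{ε, J_i} ),

synthesizes a displacement with this prescribed Jacobian by a
Poisson-preconditioned monotone search, inverts it by fixed-point
iteration, and resamples the corrected reference and the per-subject
composed fields. Around this core it provides:

* displacement-field algebra on anisotropic grids: spacing-normalized
  Jacobians, composition, inversion, warping (`jacobian_determinant`,
  `compose_fields`, `invert_field`, `warp`);
* pairwise multi-channel registration minimizing an SSD + diffusion energy
  E = Σ_c w_c Σ_p (I_fix − I_mov(p+u))² + λ Σ_{(p,q)} ‖u(p) − u(q)‖²
  with a monotone coarse-to-fine minimizer (`register`, `energy`);
* orchestration: initial-reference selection by median fat mass and
  height, half-voxel resampling, single-shot correction and iterated
  refinement with accumulated resampling (`select_initial_reference`,
  `build_reference`, `iterate_reference`, `run_pipeline`);
* the evaluation suite: symmetric volume change V, AAVC (plain and
  MAD-robust), inverse consistency error, MSE, mutual information, Dice
  with strict-majority label fusion (`aavc`, `aice`, `mse`,
  `mutual_information`, `dice`, `majority_vote`);
* seeded synthetic phantoms and diffeomorphisms with known ground truth,
  so everything is testable without any dataset (`make_phantom`,
  `make_diffeomorphism`, `make_cohort`, `make_analytic_field`);
* NIfTI I/O with grid metadata and a command-line front end
  (`inst/cli/avref.R`).

See the vignette `vignettes/average-volume-reference.Rmd` for the model,
the algorithmic choices and their rationale.

## Worked example

```r
library(avref)

# a 32^3 body phantom and four seeded fold-free deformations
spec    <- phantom_spec(shape = c(32, 32, 32), seed = 1)
phantom <- make_phantom(spec)
mask    <- channel(phantom$image, "mask") > 0.5
fields  <- lapply(1:4, function(s)
  make_diffeomorphism(spec$shape, spec$spacing, magnitude_mm = 6,
                      min_jacobian = 0.25, seed = s))

# correct the reference so the average volume change vanishes
res <- build_reference(phantom$image, fields, synthesis_config(mask = mask))
print(res)
#> <reference_result> 4 subjects
#>   synthesis: 8 iterations, max Jacobian mismatch 0.00965
#>   mean AAVC before/after: 0.05349 / 0.0451

Js <- lapply(res$composed_fields, function(f) jacobian_determinant(f)$values)
gm <- exp(Reduce(`+`, lapply(Js, log)) / length(Js))
mean(gm[res$report$roi_after])
#> [1] 0.99969
```

The synthesis matched the prescribed mean Jacobian to below the 0.01
tolerance in 8 iterations; the per-subject average absolute volume change
drops after correction; and the voxel-wise geometric mean of the composed
Jacobians over the body is 1 to three decimals — the zero-average-volume
property the reference is built for.

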