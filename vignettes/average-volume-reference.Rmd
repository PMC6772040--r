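---
title: "Average-volume reference spaces: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Average-volume reference spaces: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avref)
```

## The problem

Voxel-wise statistical analysis of cohorts of whole-body volume images
(e.g. fat/water separated MR) requires a common coordinate system: every
subject is mapped to a reference space by deformable registration, and
quantities such as local tissue volume are read off the mappings. Local
volume is carried by the Jacobian determinant of the deformation, so any
systematic volume bias of the reference itself contaminates downstream
correlation analyses. The goal of this package is a reference space that is
*neutral with respect to local volume*: at every voxel, the average volume
change over the mappings to the whole cohort is zero.

## Model

A deformation is written as the identity plus a displacement,
$f(x) = x + u(x)$, stored as a dense vector field in physical units (mm) on
the reference grid. Its Jacobian determinant $J[f](x) = \det(\partial f_i /
\partial x_j)$ is the local volume-change ratio: 1 means no change, above 1
expansion, in $(0,1)$ contraction, and values at or below 0 a folding,
physically infeasible mapping.

Let $f_1, \dots, f_n$ register the cohort subjects to an initial reference
$I_R$, and let $d$ deform $I_R$ into a corrected reference $I_{R'}$. The
subject mappings from the corrected space are the compositions
$f_j \circ d^{-1}$, and their Jacobians multiply as
$\prod_i J[f_i \circ d^{-1}] = \prod_i J[f_i] \cdot J[d]^{-n}$. Imposing
this product to be 1 — zero average pointwise volume change — forces $J[d]$
to equal the voxel-wise *geometric mean* of the $J[f_i]$. The pipeline is
therefore:

1. compute $J_i = J[f_i]$ (`jacobian_determinant`),
2. average them under logarithm with a lower clamp $\epsilon$
   (`mean_jacobian`): $\bar J = \exp\big(\tfrac1n \sum_i \ln \max\{\epsilon,
   J_i\}\big)$,
3. synthesize a displacement $d$ whose Jacobian matches $\bar J$
   (`displacement_from_jacobian`),
4. invert $d$ and resample the corrected reference and the composed
   per-subject fields (`build_reference`).

The clamp is a *lower* threshold: it removes singularities caused by local
folds ($J_i \le 0$) from imperfect registrations, which would otherwise
make the logarithm undefined. Its default, $\epsilon = 0.01$, corresponds
to treating any compression beyond 100:1 as untrustworthy registration
output rather than anatomy.

## Prescribed-Jacobian synthesis

Generating a deformation with a prescribed Jacobian is ill-posed without
boundary conditions. We fix $u = 0$ on the grid boundary, which makes the
deformation globally volume preserving, so a feasible target must have
grid-wide mean 1. The target is made feasible by uniformly rescaling the
values *outside* the body mask, leaving the anatomically meaningful
prescription inside the body untouched (with no mask the whole target is
rescaled multiplicatively). Matching is enforced on the mask intersected
with the grid interior — the boundary shell is excluded because $u$ is
pinned there — and the background Jacobian floats freely, absorbing the
global constraint.

The search iterates a gradient-type correction. With $r = \bar J - J[id+u]$
restricted to the enforced voxels, a potential $\varphi$ solves the Poisson
problem $\nabla^2 \varphi = r$ with homogeneous Dirichlet conditions
(diagonalized exactly by a type-I discrete sine transform, applied as dense
matrix products — grids here are small), and the update is $u \leftarrow u
+ s\,\nabla\varphi$. To first order $J[id+u] \approx 1 + \nabla\!\cdot u$,
so this is an approximate Newton step on the smooth part of the residual;
the step $s$ is halved until the mismatch objective $\sum_{\text{enforced}}
(J - \bar J)^2$ decreases, making the objective trace monotone
non-increasing by construction. Iteration stops when the maximum absolute
mismatch over the enforced voxels is at most `tol` (default 0.01) or at
`max_iter` (default 500). The procedure is deterministic given the target
and configuration. On the cohort targets exercised in the tests it
converges in well under ten iterations.

Displacement-field inversion uses the classical fixed-point scheme
$v_{k+1}(x) = -u(x + v_k(x))$ from $v_0 = -u$, stopping when the maximum
update drops below `tol` (default 0.1 mm, `max_iter` 50). On fold-free
fields with moderate compression the composition residual
$\|f \circ f^{-1} - id\|$ lands well below a tenth of a voxel.

## Registration

Pairwise registration minimizes a multi-channel sum-of-squared-differences
data term plus a diffusion regularizer over 6-connected neighbour pairs:

$$E(u) = \sum_{c} w_c \sum_p \big(I^{fix}_c(p) - I^{mov}_c(p + u(p))\big)^2
  + \lambda \sum_{(p,q) \in \mathcal N} \|u(p) - u(q)\|^2 .$$

Any monotone minimizer of this energy is admissible — the reference
construction consumes only the resulting fields — and the implementation
uses line-searched gradient descent over a coarse-to-fine pyramid (default
3 levels, x2 downsampling). The backtracking line search accepts a step
only when the energy decreases, and the returned field is replaced by the
initialization if refinement could not improve on it, so
`energy(result) <= energy(init)` holds unconditionally. Warm-starting from
the composed fields of a previous correction round shortens later
iterations substantially. Defaults are equal channel weights and
$\lambda = 1$; channels on an absolute-content scale (0–100, as for
fat/water fraction images) make this balance meaningful, which is why the
phantom generator produces intensities on that scale. The optimizer is
deterministic; the `seed` field of the configuration is recorded for
provenance only.

## Orchestration

The initial reference is the cohort subject closest to both the median fat
mass and the median height, scored as the sum of absolute robust z-scores
$|x - \mathrm{med}| / \mathrm{MAD}$ (plain MAD, i.e. `constant = 1`; a zero
MAD is treated as 1). "Closest to both" does not prescribe a combination
rule; the additive robust z-score is this package's explicit choice, is
deterministic, and breaks ties by subject id.

Because every synthetic reference is produced by resampling, while the
initial reference is not, image-similarity comparisons between the two
would be biased by interpolation smoothing. The initial reference is
therefore shifted by half a voxel along every axis with linear
interpolation (`halfvoxel_resample`) before any registration: anatomy is
unchanged, smoothing is equalized. The shift is applied once, to the
initial reference only, not re-applied at later iterations.

Iterated refinement (`iterate_reference`) repeats register → correct,
warm-starting registrations from the previous composed fields and
*accumulating* the correction: the reference at iteration $k$ is always a
single warp of the (half-voxel resampled) initial image through the
composed inverse deformations, never a warp of the previous reference, so
each reference carries exactly one interpolation pass regardless of the
iteration count. The body mask is carried along by nearest-neighbour
warping so the enforced region follows the deforming anatomy. The per-
iteration mean AAVC trace has length `n_iters + 1`, with entry 0 measured
on the initial registration.

## Evaluation metrics

Since the Jacobian treats compression and expansion asymmetrically, volume
changes are compared through the signed symmetric transform $V = J - 1$ for
$J \ge 1$ and $V = 1 - 1/J$ for $J \in (0, 1)$, so that $|V(J)| =
|V(1/J)|$. The average absolute volume change (AAVC) of a mapping is the
ROI mean of $|V|$; the robust variant excludes voxels whose $|V|$ differs
from the ROI median by more than 2.5 plain MADs (a zero MAD excludes
nothing; if everything would be excluded the plain AAVC is returned with a
warning). The inverse consistency error AICE$(h, h_I)$ is the ROI mean of
$\|(h_I \circ h)(x) - x\|$ in mm. MSE is the ROI mean squared intensity
difference. Mutual information uses a 256x256 joint histogram within the
ROI with per-image intensity ranges and the natural-log convention — the
base is not canonical and affects only the scale; a constant image
occupies a single bin and yields MI = 0 rather than an error. Note that
the plug-in MI estimate carries a positive finite-sample bias of roughly
$(B-1)^2/2N$ nats for $B$ bins and $N$ samples; independence checks in the
tests therefore use a bin count at which the bias is negligible. Label
fusion uses strict-majority voting: a voxel keeps a label only if more than
half of the warped segmentations agree, and falls back to background
otherwise — a rule under which an inconsistently mapped structure can
disappear from the fused labelling entirely.

## The phantom generator

`make_phantom` builds a deliberately schematic body: an ellipsoidal body
mask (fraction 0.1–0.6 of the grid), a subcutaneous fat shell and an
interior water compartment with smooth large-scale gradients, a few
ellipsoidal organs of distinct intensity, band-limited edges (a finite
acquisition PSF) and a smooth seeded intensity texture — spatially
correlated fluctuations survive subvoxel resampling, unlike white noise,
and anchor the registration in flat regions. Channels emulate absolute
fat/water content on a 0–100 scale; the default grid is $48^3$ voxels at
the anisotropic 2.07 x 2.07 x 8.00 mm spacing of whole-body MR protocols,
so spacing-normalized derivatives are genuinely exercised.
`make_diffeomorphism` draws Gaussian-smoothed seeded random fields, tapers
them to zero at the boundary, and shrinks the amplitude by bisection until
a requested minimum Jacobian holds, guaranteeing fold-free ground truth.
`make_cohort` warps one template through the *inverses* of the ground-truth
fields, so the field registering subject $j$ back to the template is
exactly the returned ground truth. All generators are bit-reproducible
under fixed seeds.

What the phantoms do **not** model: MR intensity inhomogeneity,
through-plane partial-volume structure finer than the slice spacing,
inconsistent subject pose, or limbs leaving the field of view — all real
failure modes of whole-body registration. Passing tests on phantoms
demonstrate the correctness of the field algebra and of the volume-change
bookkeeping, not clinical-grade registration accuracy.

## Numerical choices

* Derivatives: central differences at interior voxels, one-sided at the
  boundary, divided by the per-axis spacing; the Jacobian map keeps the
  grid shape.
* Interpolation: trilinear for intensities and vector components, nearest
  for labels (labels may never be interpolated linearly). Out-of-support
  samples clamp to the nearest border for vector fields (no spurious folds
  at the support edge) and take a constant fill (default 0) for
  intensities.
* Coordinates: voxel index $i$ (0-based) sits at `origin + i * spacing`;
  displacements are stored in mm — on 2.07 x 2.07 x 8.00 mm voxels a
  voxel-unit Jacobian would simply be wrong.
* Problem sizes: the shipped tests and the acceptance script use $48^3$
  cohorts of five subjects with three refinement iterations, and $32^3$
  grids for synthesis oracles — small enough to re-run routinely on one
  CPU, large enough that boundary effects do not dominate.
* The reference subject itself is not re-registered to its own reference
  in the pipeline; it would contribute a null row.

## Known limitations

Alignment along a coarsely sampled axis (8 mm slices) is signal-limited:
intensity gradients along that axis are weak, and the through-plane
component of a deformation is recovered much less accurately than the
in-plane components — consistent with the general difficulty of
whole-body registration in the thorax and abdomen. The correction step is
exact only up to the synthesis tolerance, the inversion tolerance and the
interpolation error of composing discrete fields; the tests budget 0.05 in
absolute geometric-mean units for the combined effect. Affine
pre-alignment, 2-D grids and resampling kernels beyond linear/nearest are
out of scope.
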