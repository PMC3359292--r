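---
title: "Coupling joint-scale deformation to chondrocyte mechanics: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling joint-scale deformation to chondrocyte mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cellscale)
```

`cellscale` implements a one-way, first-order coupling between a macro-scale
hexahedral finite element solution (a loaded joint, in the motivating
application) and many independent micro-scale models of chondrocytes in
cartilage matrix. This vignette records the modelling decisions, their
rationale, and what the package's verification does and does not
demonstrate.

## 1. The coupling model

The macro solution enters only through nodal positions: the undeformed
configuration `X` and the deformed configuration `x` of a hexahedral mesh.
For each element of a user-chosen set, the deformation gradient

$$F(\xi) \;=\; \Big(\textstyle\sum_a x_a \otimes \nabla_\xi N_a\Big)
               \Big(\textstyle\sum_a X_a \otimes \nabla_\xi N_a\Big)^{-1}$$

is sampled at the element centroid (default) or at the eight Gauss points.
`F` is exact wherever the underlying motion is affine; otherwise it is the
gradient of the trilinear interpolant, and centroid sampling aliases
within-element variation. `variation_residual()` quantifies that variation
as the largest componentwise-absolute-sum difference over the 28 unique
pairs of Gauss-point tensors, which is the practical check on whether
centroid sampling is adequate for a given element.

The coupling is first order: each micro block sees a *uniform* `F` as the
affine Dirichlet condition `u = (F - I)X` on all six faces. Gradients of
`F` across the macro element, and any time history, are discarded. This is
appropriate for an elastic, single-time-point analysis and is what makes
the micro jobs embarrassingly parallel.

Elements are only worth a micro solve if they deform:
`filter_deforming_elements()` keeps elements whose `F` deviates from the
identity by more than `tol` in any component. The default `tol = 1e-3`
excludes numerical noise from the macro solver while retaining any
mechanically meaningful state (0.1% strain); it is configurable because the
right value depends on the macro solver's convergence tolerance.

## 2. Micro geometry

The micro construct is a 100 μm ECM cube containing `n` chondrons (a
chondrocyte sphere plus a concentric PCM shell). Defaults: cell radius
7.5 μm and PCM thickness 3.3 μm, giving a chondron radius of 10.8 μm.
These values make the analytic ECM volume fractions 99.47% for one chondron
and 94.20% for eleven — matching, at their printed precision, the reference
fractions of 99.5% and 94.2% — and are mutually consistent with a mesh in
which the cell spans 9 elements across its diameter while the PCM spans 2
through its thickness. Eleven cells is the mean count for a middle-zone
block of this size.

Multi-chondron placement is rejection sampling with two constraints:
pairwise surface separation of at least one PCM thickness, and at least one
PCM thickness of clearance to the block boundary (`min_separation` and
`boundary_margin`, both configurable; 10,000 attempts per chondron before a
`PackingInfeasible` error). The seed is part of the geometry object and its
provenance, so one fixed random construct can be reused across an entire
batch — per-cell metrics are then comparable across macro elements.

**Voxel meshing.** The block is meshed as a structured `r³` grid and each
element is labelled by the region of its centroid. This deliberately
replaces boundary-conforming meshing: it is robust for arbitrary random
N-cell geometries, and its error mode (stair-stepped interfaces) is
controlled by resolution. Labelled region volumes converge to the analytic
sphere/shell volumes with an `O(1/r)` envelope, which the tests verify —
with a caveat: the convergence is oscillatory, because the error depends on
how the sphere surface sits relative to the centroid lattice. Even
resolutions place a centred chondron on a grid node (cell volume error
−5.8% at `r = 50`, +20% at `r = 40`); odd resolutions centre it in a voxel
(−0.9% at `r = 75`). Aspect-ratio *changes* are far less sensitive than
volumes, since the same voxelization measures both configurations. The
trade-off of voxel meshing is
that interface stresses are noisier than with a conforming mesh, so
volume-averaged metrics are the intended outputs. Below `r ≈ 12` a 7.5 μm
cell can lose all its voxels; `build_micro_mesh()` warns in that case and
refuses `r < 10`.

## 3. Constitutive model and solver

All regions follow the uncoupled Mooney–Rivlin model
`W = c₁(Ī₁−3) + c₂(Ī₂−3) + U(J)` with the volumetric energy
`U(J) = (K/2)(ln J)²`, chosen for good behaviour in strong compression
(its pressure `K ln J / J` stiffens as `J → 0`). Coefficients are per
region (MPa); `scale_material_table()` produces uniformly scaled variants
(preserving inter-region ratios) and `reduce_pcm_stiffness()` the
PCM-softened variant used in the sensitivity protocol.

The element is an 8-node hexahedron with a mean-dilatation treatment: the
isochoric energy is integrated at the 2×2×2 Gauss points, while `U` is
evaluated once per element at the volume-averaged Jacobian
`J̄ = v_e / V_e`. With ECM `K/c₁ ≈ 49` (equivalent Poisson ratio ≈ 0.48) a
fully integrated displacement element locks volumetrically; the
mean-dilatation element does not, and the patch test still passes exactly
for every material.

The discrete problem is the stationarity of a well-defined element energy,
so the residual is its exact gradient, and the tangent is obtained by
central finite differencing of that exact element residual (step
`10⁻⁶ · Vₑ^{1/3}`). This keeps the tangent consistent with the
mean-dilatation coupling at negligible implementation risk; the cost is a
constant factor in assembly, not in the dominant sparse factorization.

Newton flow, per load increment:

* **Warm start.** For affine boundary conditions the full field is seeded
  with `u = (F−I)X`, which is the exact solution of the homogeneous
  problem; the Newton iteration then only resolves the inclusion-induced
  perturbation. The patch test converges in zero iterations this way.
* **Quasi-Newton reuse.** The CHOLMOD factorization of the tangent is
  reused across iterations while the residual contracts by at least
  `refactor_ratio` (default 0.8) per iteration; otherwise the tangent is
  reassembled and refactorized (reusing the symbolic analysis). If CHOLMOD
  reports an indefinite matrix — which happens transiently when a step
  starts far from equilibrium — that iteration falls back to a sparse LU
  direction.
* **Line search.** Backtracking on the residual norm, also rejecting any
  state with a non-positive Jacobian at a Gauss point. A failed line search
  on a stale tangent triggers refactorization rather than failure.
* **Containment.** Mechanical non-convergence, non-finite boundary data,
  or `det F ≤ 0` in the driving tensor produce `status = "failed"` with
  diagnostics; only structural errors (bad mesh, missing materials) raise.

Defaults are 10 equal increments, relative residual tolerance 10⁻⁶ (with a
small absolute floor scaled by `max(c₁)·V^{2/3}`), and 25 iterations per
step. For the mild strains of the batch protocols (≤ 30% nominal) the
affine warm start makes 1–2 increments sufficient, and the package's own
studies run that way; the conservative default suits cold starts and mixed
boundary conditions.

Verification rests on analytic oracles rather than comparison with any
particular production solver: the patch test (exact affine reproduction,
uniform stress equal to the closed-form Cauchy stress), a mesh-free 1D
energy-minimization oracle for unconfined uniaxial loading (matched to
0.1%), the incompressible-limit kinematics `λ_lat → λ^{-1/2}` as `K` grows,
invariance under node renumbering, and energy-consistency of the stress via
numerical differentiation of `W`. At the study's finite `K/c₁ = 49.3` the
compressible model genuinely deviates from the *incompressible* closed-form
axial stress by about 0.3% at λ = 0.8 and 2.4% at λ = 1.2 — an inherent
property of the material (`J−1 ≈ p/K`), not a solver error.

## 4. Deformation metrics

* **Volumetric strain** (per cell set): `(ΣV_def − ΣV_undef)/ΣV_undef`,
  with centroid-rule element volumes (`8·det J(0)`) in both
  configurations — the same rule in numerator and denominator, so the
  quadrature bias largely cancels.
* **Shape.** The unit-density moment-of-inertia tensor is assembled from
  element centroids and volumes about the set centroid and inverted through
  the solid-ellipsoid relations (`a² = 5(λ₁+λ₂−λ₃)/(2m)` and permutations,
  eigenvalues descending) to best-fit semi-axes `a ≥ b ≥ c`. Aspect-ratio
  changes are deformed minus undeformed ratios for major/minor,
  major/middle, middle/minor. Because both configurations are measured with
  the same voxelization, discretization bias in the ratios largely
  subtracts out: a sphere mapped by `diag(1.1, 1.1^{-1/2}, 1.1^{-1/2})`
  yields ΔAR(major–minor) = 0.1537 at 44 elements across the diameter,
  versus 2·(1.1)^{3/2}/2.2 − 1 ≈ 0.1537 exactly.
* **Effective scalars.** One formula serves stress and strain:
  `√(((p₁−p₂)² + (p₂−p₃)² + (p₁−p₃)²)/2)` from the principal values — the
  von Mises form without the (2/3)-scaled "effective strain" variant some
  codes use. The choice is deliberate (one formula for both quantities);
  note any cell/ECM *ratio* of effective strains is invariant to that scale
  choice. Maximum shear is the tensorial `(p₁−p₃)/2`. Strain is
  Green–Lagrange `E = ½(FᵀF − I)`; stress is Cauchy, evaluated at the
  element centroid with the mean-dilatation `J̄` substituted for the local
  `J` (consistent with the element's energy).
* **Volume averaging** over a set weighs each element by its *deformed*
  volume: `Σ(v_e m_e)/Σ v_e`.

Principal values of the many per-element 3×3 tensors are computed with the
closed-form trigonometric eigenvalue solution (vectorized), cross-checked
against `eigen()` in the tests.

## 5. Batch, summaries, and protocols

`run_batch()` maps every filtered macro element to one micro job sharing a
single fixed geometry and mesh, executes jobs with `parallel::mclapply`
(no inter-job state), and records per-job status in a manifest (optionally
JSON on disk). Results are row-bound in element order, so the table is
bitwise-identical for any worker count; a failed job contributes a manifest
row and no result rows.

Summaries follow the study's analyses: through-origin least squares
(`slope = Σxy/Σx²`, with its sum of squared residuals as the spread
measure), per-cell regressions reported as min/avg/max slopes, and
five-number quartile summaries using linear interpolation between order
statistics (`stats::quantile` type 7 — the convention had to be chosen, and
this is R's default and the most common one).

`sensitivity_study()` reruns one 11-chondron construct under 10% nominal
compression with volume-preserving lateral expansion
(`F = diag(0.9^{-1/2}, 0.9^{-1/2}, 0.9)`, det F = 1) for a reference
material table, a ×10 uniformly scaled table, and a PCM/10 table, reporting
quartiles of per-cell cell/ECM effective-strain ratios. Uniform scaling
leaves the ratios nearly unchanged (hyperelastic displacement-driven
problems are scale-invariant up to the `K/c₁`-fixed compressibility);
softening only the PCM reduces cell strain, because the soft shell then
absorbs relatively more of the imposed deformation.

## 6. Synthetic data: what it emulates, what it does not

`synthetic_macro_solution()` manufactures macro states on slab meshes from
closed-form deformation fields (affine, uniaxial, simple shear, combined,
quadratic bending) whose exact `F(X)` is available as an oracle. These
fixtures emulate the *interface* a real joint model presents — nodal
positions on hexahedra, element sets, VTK/CSV files — and make extraction
errors measurable exactly. They do not emulate contact-driven strain
concentrations, anatomical geometry, or macro-solver noise, so passing
tests demonstrate correctness of the pipeline's operations, not validity of
any particular joint model. A quirk worth knowing: for a *quadratic*
bending field the centroid-sampled `F` is exact (the trilinear interpolant's
gradient at the centroid matches the mean gradient), so the refinement
study in the tests uses a sinusoidal field instead, where the expected
first-order (observed second-order) convergence is visible.

The canonical micro load cases are fixed: (a) −30% nominal z strain with
free lateral faces — mixed boundary conditions (only z-faces prescribed,
symmetry supports on two lateral faces), a deliberate extension beyond the
all-face affine transfer, needed for unconfined-compression verification;
(b) 10% volume-preserving compression (affine, det F = 1); (c) simple
shear.

## 7. Problem sizes and defaults used in the package's own studies

The shipped tests and studies run the single- and 11-chondron constructs at
`r = 30` (27,000 elements, ~90k degrees of freedom), five compressive
volume-preserving loads at 2–10% nominal strain for the
amplification/shielding trends, and `r = 30` for the three-case sensitivity
protocol — sizes chosen so the whole verification suite completes on a
desktop core in minutes while keeping ≥ 4 elements across a cell diameter.
At these sizes the observed trends (cell strain amplification of ~2× over
ECM; multi-cell strain shielding of roughly 10–20% in aspect-ratio change)
are stable in sign across loads and seeds, which is what the trend tests
assert; magnitudes tighten with resolution.

## 8. Known limitations

* One-way, first-order coupling only: no homogenization feedback, no
  gradient-of-`F` enrichment, no time history (hence no poro- or
  visco-elasticity).
* Voxel interfaces: pointwise interface stresses are stair-step noisy;
  use volume-averaged quantities.
* Spherical, isotropic cells and shells; no zonal shape variation, no
  fiber architecture at either scale.
* The deformation-threshold default (10⁻³) and the quantile convention are
  conventions, stated and configurable rather than derivable.
* `mclapply` parallelism forks processes; on platforms without fork the
  batch runs serially (results are identical by construction).
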