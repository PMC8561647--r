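---
title: "Focality-optimized TMS coil placement: model, numerics and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Focality-optimized TMS coil placement: model, numerics and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tmsfocal)
```

This vignette is the package's own account of the science it implements:
the quasistatic forward model, the inverse-problem search, the metrics,
the synthetic phantoms that stand in for segmented head models, and the
numerical choices behind each — including what the phantom-scale tests do
and do not demonstrate about real heads.

## The physical model

A TMS coil driven with current slew rate $dI/dt$ induces an electric
field in the head. In the quasistatic regime the total field splits into
the free-space (primary) part and the field of the charge that
accumulates on every conductivity interface:

$$\mathbf E(\mathbf r) = \mathbf E_p(\mathbf r)
  + \sum_k \frac{g_k A_k}{4\pi}\,
    \frac{\mathbf r-\mathbf c_k}{|\mathbf r-\mathbf c_k|^3},
\qquad
\mathbf E_p(\mathbf r) = -\frac{\mu_0}{4\pi}\,\frac{dI}{dt}
  \sum_j \mathbf m_j \times \frac{\mathbf r-\mathbf p_j}
  {|\mathbf r-\mathbf p_j|^3},$$

where the coil is a cloud of magnetic dipoles $(\mathbf p_j, \mathbf
m_j)$ (moments per unit current, the CCD convention) and $g = \rho /
\varepsilon_0$ is the scaled surface charge density on facet $k$ with
area $A_k$ and centroid $\mathbf c_k$. Storing $\rho/\varepsilon_0$
keeps $\varepsilon_0$ out of the linear system entirely. The interface
condition on the normal current yields, for collocation facet $m$ with
conductivities $\sigma^-$ (inside) and $\sigma^+$ (outside),

$$g_m\,\frac{\sigma^-+\sigma^+}{2(\sigma^--\sigma^+)}
 - \mathbf n_m\cdot\!\!\sum_{k\ne m} g_k\,\mathbf K_k(\mathbf c_m)
 = \mathbf n_m\cdot\mathbf E_p(\mathbf c_m).$$

Interfaces without conductivity contrast carry no charge and are dropped
from the system (with a message).

### Numerical realization

* **Near integrals.** $\mathbf K_k$ is the centroid point kernel for
  well-separated pairs and the *exact* field of a uniformly charged flat
  triangle — a signed solid angle for the normal part plus per-edge
  logarithmic terms for the in-plane part — whenever the evaluation point
  is within `near_mult = 4.5` (≈ three edge lengths) of
  $\sqrt{A_k}$. The same kernel serves matrix assembly and field
  evaluation, so observation points that sit a millimetre above a facet
  are integrated exactly; a unit test checks the kernel against a dense
  barycentric quadrature.
* **Facet-averaged testing.** The collocation equation is averaged over
  six barycentric subcentroids of the test facet. For thin, closely
  spaced shells (the CSF–GM–WM sandwich is 2–2.5 mm at ~10 mm facet
  size) this averaging reduces the field error at mid-cortex by roughly a
  factor of five at no memory cost; the right-hand side can stay at the
  centroid because the primary field is smooth on the facet scale.
* **One factorization per head.** The dense operator is LU-factorized
  once (`Matrix::lu`); each candidate pose afterwards costs one
  right-hand-side solve plus field evaluation — a few hundred
  milliseconds at the default ~9 000 facets. Relative residuals are
  checked against 1e-8 on every solve.
* **Per-shell resolution.** The skin boundary (insulating interface,
  largest charge density) is meshed one subdivision level finer than the
  CSF/GM/WM shells, and the smooth resistive skull one level coarser.
  This allocation was chosen as the coarsest one meeting the forward
  accuracy contract below; it is configurable through
  `phantom_spec(mesh_density =)`.

### The sphere oracle

For *any* spherically symmetric conductivity profile, the field induced
inside by an external magnetic dipole has a closed form (the reciprocal
of the classical magnetically-silent-sphere result); it is purely
tangential and independent of the radial profile. This makes the
five-shell sphere phantom an exact validation case: the acceptance suite
requires the BEM total field to match the oracle within 3 % relative L2
error at the default mesh density on the mid-cortex surface. At the
default density the measured error is ≈ 2.4 %, and it tightens with
refinement.

## The inverse problem

`run_ip()` chains the stages:

1. **Sulcus-aligned initial placement** — the projection construction
   used in motor mapping: centerline through the target, perpendicular
   to the skin at the centerline–skin intersection, coil bottom
   10 ± 0.25 mm from the skin, and the coil handle (the direction of the
   dominant induced field) perpendicular to the nearest sulcal wall. On
   the gyrus phantom the wall normal is available in closed form from
   the trench profile; on rotationally symmetric heads the yaw is
   degenerate and is flagged, never silently resolved. The coil model
   separates the winding plane from the casing bottom (`casing_depth`,
   6 mm for the presets): the placement standoff is measured to the
   casing while the safety constraint applies to the metal windings.
2. **Sequential coordinate descent** — per pass the variables are probed
   in the order φ, α, β, x, y, z at ±0.1 rad / ±2 mm; the minimizer of
   each three-point probe is adopted immediately, ties keep the current
   value (preventing drift on flat plateaus), and passes repeat until
   the per-pass AAD decrease drops below 0.05 mm (far below mesh
   resolution) or the pass cap is reached. Any pose whose winding-to-
   scalp clearance falls below 10 mm receives a `+Inf` cost sentinel and
   is excluded without a forward solve. A restricted `tangential3` mode
   varies only yaw and two scalp-tangential translations, re-normalizing
   the centerline to the skin after each move.
3. **Stability correction** — the defocalization
   $DF_{coil} = \mathrm{mean}_{n=0:12}\, AAD_n / AAD_{final}$ over the
   unperturbed pose and the twelve ±1.5 mm / ±0.1 rad perturbations
   (infeasible perturbations are skipped with a message). If the last
   iteration has $DF \ge 1.25$ the solution is reverted one accepted
   update at a time until the bound holds (config-switchable to whole-
   pass reversion). Ratios are *not* clamped at one: at a non-optimal
   pose perturbations can reduce the AAD, and raw means slightly below
   one are reported as-is.
4. **Metrics** — AAD, ARD, field loss, peak deviation (distance from the
   target to the unweighted centroid of the nodes at or above the 99th
   magnitude percentile), the defocalization at both the initial and the
   accepted pose, and the corrected focality improvement
   $1 - (DF^{final} AAD_{final})/(DF^{initial} AAD_{initial})$.

The threshold always refers to the *current* field's own maximum,
recomputed for every pose; a fixed reference from the initial pose would
change the meaning of the cost during the search.

An exhaustive grid search (`exhaustive_search`, capped at 5 000 poses)
is retained purely as the validation oracle; the test suite checks that
the descent lands within one grid step's cost of the grid optimum.

## Synthetic phantoms

The generator emulates the *geometric* structure the method relies on,
not anatomy:

* **Sphere head** — five nested icosphere shells at radii 92 / 86 / 82 /
  80 / 77.5 mm (skin, skull, CSF, GM, WM), conductivities 0.465 / 0.010 /
  1.654 / 0.276 / 0.126 S/m (standard literature defaults — configuration
  values, not ground truth). The seed perturbs the global size by ±2 %
  and the 2.5 mm GM–WM gap by ±10 %, emulating inter-subject
  variability; a given seed is bit-reproducible.
* **Gyrus head** — the same head with two Gaussian-profile trenches
  (depth 10 mm, width 12 mm, ridge length 70 mm, seeded orientation)
  carved into the GM and WM shells, leaving a gyral crown between them.
  The smooth analytic profile yields closed-form sulcal-wall normals,
  which anchor the placement tests.
* **Targets** — stepped along the crown polyline at exactly 10 mm
  straight-line (chord) spacing, centered on the crown. The generator
  *maintains* the spacing exactly, so the mean is 10 mm and the spread
  essentially zero (the reference setting tolerates a spread below
  1.2 mm); interior targets carry two neighbours, edge targets one, and
  the somatotopy metric averages over whatever neighbours exist.

What the phantoms do **not** emulate: realistic cortical folding beyond
a single gyrus, ventricles (supported by the data model, omitted by
default), tissue anisotropy, and segmentation noise. Passing tests on
phantoms therefore demonstrate the correctness of the machinery — the
solver against the sphere oracle, the descent against exhaustive search,
the metric algebra against enumeration — not clinical performance on
individual anatomy.

## Observation surfaces and sampling resolution

Observation nodes are built from the gray-matter facet centroids, moved
along the shortest vector to the 1:36-refined white-matter centroid
cloud by a fraction f = 0.5 (1:1 mid-surface, ≈ L2/3) or f = 0.8 (4:1
surface, ≈ bottom of L5; the 4:1 ratio is read as gray-side : white-side
distance). Points whose gray-to-white distance exceeds a 6 mm
cortical-thickness cap are excluded.

The cost is a mean over a *discrete* suprathreshold node set, so it only
responds to a 2 mm pose probe if set membership can change at that
scale. At phantom resolution (~10 mm facets) the uniform mid-surface is
too coarse: the hot spot spans a handful of nodes and the cost is
piecewise constant. The pipeline therefore refines the observation
sampling locally — gray-matter facets within 35 mm of the target are
barycentrically subdivided twice (≈ 1.8 mm node spacing) before node
construction — which restores a usable cost landscape without touching
the forward discretization. The hot-spot ring of every pose the search
visits stays well inside the refined region; distant nodes remain part
of the cost at their native resolution, so secondary maxima still
register. At production mesh densities (sub-millimetre cortical meshes)
no focus refinement would be needed.

A side effect of the coarse phantom sampling is that the four nearest
nodes used for the target field value span a few millimetres more than
they would on a sub-millimetre cortical mesh; the averaging-domain size
quoted for the reference setting (just under 3 mm) is recovered only
inside the refined region.

## Problem sizes and runtimes

The default phantom discretizes to ≈ 9 300 facets (skin 5 120, skull
320, CSF/GM/WM 1 280 each). Assembly takes ~10 s and the LU
factorization about a minute on one core; a pose evaluation costs a few
hundred milliseconds. A full inverse run saturates in 3–6 passes
(60–90 pose evaluations with the pose cache). The batch used by the
stability checks — six crown targets on the seed-7 gyrus phantom plus
one target on each of four further seeds, ten runs in all — completes in
roughly a quarter of an hour on one core. These sizes were chosen as the
smallest at which the forward accuracy contract holds; every dimension
(density, element counts, batch size) is configurable upward.

## Numerical choices and edge cases

* **Tie-breaking**: a three-point probe keeps the current value on ties.
* **Saturation**: per-pass AAD decrease < 0.05 mm, or the pass cap
  (12 in the batch configuration; doubling to 12 from 6 changes the mean
  final AAD by well under 5 %, the self-convergence criterion).
* **Defocalization mean**: 13 terms including the unperturbed ratio
  (exactly 1); the 12-term variant is available
  (`df_include_unperturbed = FALSE`) and differs by < 1 %.
* **Degenerate inputs**: all-zero fields make the threshold undefined
  (error); targets without neighbours make ARD undefined (error, and
  `run_ip` records `NA`); a coil below the clearance bound at the
  *initial* pose aborts the run rather than starting from an infeasible
  point.
* **Infeasible stability perturbations** are skipped with a message —
  at a pose sitting near the clearance boundary up to half the
  perturbations may be excluded, and the mean is taken over the rest.
* **Rotation convention**: `p_head = R_y(roll) R_x(pitch) R_z(yaw)
  p_local + center`; yaw acts first, about the coil normal, so
  `yaw = π` flips the handle and leaves the centerline. Any consistent
  convention would do; this one is fixed and serialized with every
  report.
* **Determinism**: phantoms, placement and search contain no hidden
  randomness; identical configuration and seed reproduce a report byte
  for byte (the report embeds the configuration and its hash).

## Known limitations

* The direct dense solver scales to a few tens of thousands of facets;
  beyond that an iterative solve with a matrix-free operator (or an
  FMM-accelerated one) would be required.
* White-matter anisotropy is outside the surface-charge formulation.
* The figure-8 presets are parametric stand-ins with the correct size
  ratio and topology, not manufacturer CAD reproductions; the skin-depth
  effect in the windings is not modelled.
* Cohort-level effect sizes reported for segmented human heads are not
  reproducible at phantom scale; the package validates mechanisms, and
  its phantom batches show the same qualitative behaviour (moderate
  focality improvement, small defocalization, modest somatotopy gain,
  occasional field gain instead of loss).
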