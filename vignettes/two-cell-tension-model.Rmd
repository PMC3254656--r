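---
title: "A surface-energy model of the two-cell embryo: methods and design"
author: "embryoshape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A surface-energy model of the two-cell embryo: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The two-cell stage embryo is modelled as a foam-like system of two bodies,
the anterior blastomere AB and the posterior blastomere P1, bounded by
three tensioned surfaces: the outer cortex of AB, the outer cortex of P1,
and the contact surface they share. The cortical tension of each surface
acts like the surface tension of a soap film, so the mechanical energy of
a configuration is

  E = gammaAB * A_AB + gammaP1 * A_P1 + gammaCnt * A_cnt,

the tension-weighted sum of the three surface areas. Cells are treated as
incompressible (each body's volume is fixed) and confined to a rigid
ellipsoidal eggshell through a one-sided constraint: surfaces may press
against the shell but not cross it. Equilibrium shapes are energy minima
under these constraints.

Because only relative tensions matter, gammaP1 is fixed at 1 and serves
as the unit. Two parameter regimes are distinguished: the *homogeneous*
model (all three tensions equal) — the classical double-bubble limit —
and the *heterogeneous* model, in which gammaAB and gammaCnt take
independent values. The contact can neither detach from nor engulf a cell
only while |gammaAB − gammaP1| <= gammaCnt <= gammaAB + gammaP1; all
grid searches are restricted to this region.

Pressures follow from the constrained optimum: the Lagrange multiplier of
each volume constraint is the derivative dE/dV, i.e. the excess
hydrostatic pressure of that body over the exterior. On a free spherical
patch this reduces to Laplace's law P = 2 gamma / R, and across the
contact P_AB − P_P1 = 2 gammaCnt / R_cnt. The signed *curve depth* d of
the contact surface — the quantity measured in embryos from mid-plane
images — is positive when the contact bulges from AB toward P1.

## Discretization and minimization

Surfaces are triangle meshes over a single shared vertex pool. Contact
triangles are stored once, oriented outward from AB; the P1 body uses
them with reversed sense, which keeps the two enclosed volumes consistent
by construction. The initial configuration is two cubes of side 14.7 um
sharing one face, centered in the shell and aligned with its major axis,
with AB on the anterior side.

Minimization is projected gradient descent with a backtracking (Armijo)
line search:

* the raw area gradient is first projected onto the tangent space of the
  two volume constraints (via least-squares multipliers), so steps are
  not immediately undone by the volume restoration;
* for vertices pressing against the shell, the outward normal component
  of the step is removed (active-set treatment of the one-sided
  constraint), and trial positions outside the shell are projected back
  to the nearest surface point (safeguarded 1D root finding on the
  Lagrange condition, tolerance 1e-13 on the implicit value);
* after every trial step both volumes are restored by the minimal-norm
  vertex displacement along the volume gradients (Newton iteration on
  the two multipliers, relative tolerance 1e-11). The correction is
  routed through shell-free vertices only: pushing pressed vertices
  through the shell and clamping them back stalls the Newton iteration.

The schedule follows the coarse-to-fine protocol: minimize, then three
rounds of 1-to-4 midpoint subdivision, each followed by minimization.
Between phases the mesh quality is maintained by two shape-neutral
passes: equiangulating edge flips restricted to same-patch interior
edges (patch-boundary and triple-line edges are never flipped), and
tangential vertex smoothing (Laplacian displacement with the normal
component removed; triple-line vertices move only along the triple
line), after which volumes are restored again.

Convergence is declared when the relative energy decrease over a
50-iteration window falls below 1e-9, or when the line search can no
longer find a descending step; the per-phase iteration budget is 4000
accepted steps. All schedules are deterministic — the simulator contains
no randomness. At convergence the volume residuals are below 1e-4
(typically ~1e-11) and the energy trace is non-increasing.

**Mesh resolution.** The three-round protocol is the default, but on the
strongly confined embryo geometry the equilibrium depth and pressure
ratio still move by a few percent when a fourth round is added, and by
about 1% from the fourth to the fifth. Results reported by the
acceptance script therefore use five rounds (22 528 triangles); the
package's mesh-convergence test asserts stability between rounds four
and five. Unconfined double bubbles are well converged at the default.

**Pressure extraction.** Two independent routes are implemented:
(a) the least-squares multipliers of the stationarity condition
grad E = P_AB grad V_AB + P_P1 grad V_P1, where rows of shell-pressed
vertices (implicit value within 1e-3 of the surface) are projected onto
the shell tangent plane because they additionally carry an unknown shell
reaction; and (b) central finite differences of the re-minimized energy
at volumes perturbed by ±0.5–1%. Route (a) is the reported value;
route (b) is the test oracle. The two agree to better than 1% in the
test suite, and both reproduce the Laplace closed forms on free bubbles
and isolated spheres to within 2%.

## Fitting tensions to an observed shape

Tension parameters are fitted by exhaustive grid search: gammaAB and
gammaCnt move from 0.2 to 10.0 in steps of 0.2 (grid membership is
handled through integer indices so the stability-inequality comparisons
at the grid endpoints are exact; the full grid leaves 514 valid
combinations). For each combination the model shape is minimized under
the measured volumes and eggshell, its vertices are rigidly registered
onto the membrane-contour voxels by iterative closest point (ICP), and
the combination with the smallest registration RMSE wins.

ICP uses directional nearest-neighbour correspondence (model vertices to
contour points), the orthogonal Procrustes solution per iteration, a
convergence threshold of 1e-6 um on the RMSE improvement and at most 100
iterations. Initialization tries the centroid-only identity alignment
plus the four proper principal-axes alignments and keeps the best by
RMSE: embryo point clouds are nearly axisymmetric, so covariance axes
alone cannot pin down the azimuth and the extra identity candidate makes
the per-combination RMSE landscape smooth.

A practical point surfaced by the closure tests: the measured volumes
and the target contour must come from the *same* segmentation. The
watershed contour sits systematically a fraction of a voxel inside the
true surface; constraining the models to the true generator volumes
while scoring them against that contour biases the grid argmin by two
steps in gammaCnt, whereas the self-consistent pipeline (volumes and
contour both from the segmentation, as with real stacks) recovers the
generating parameters within one grid step under rendering noise.

## Image quantification

The imaging pipeline mirrors how such stacks are processed in practice:

* Gaussian smoothing (default sigma 0.5 um — the blur scale is a free
  choice; it only needs to suppress shot noise below the ridge contrast)
  and trilinear resampling of the anisotropic confocal stack
  (0.244 x 0.244 x 0.733 um voxels) to cubic 0.733-um voxels;
* marker-based 3D watershed (Meyer flooding, 6-connectivity) on the
  membrane-intensity landscape — the membrane marker is already
  ridge-like, so no gradient transform is applied. Three manually chosen
  markers seed AB, P1 and the exterior; voxels where basins meet form a
  one-voxel boundary label;
* cell volumes by the half-boundary-corrected voxel count
  V = (N_cell + N_bnd / 2) * voxel volume, with N_bnd counted over
  boundary voxels face-adjacent to the region. On watershed-digitized
  spheres of radius 8–30 voxels the relative error stays below 1%. The
  estimator's contract covers smooth regions: on sharp-cornered regions
  (a digitized cube) the boundary layer no longer straddles the surface
  evenly and the half-voxel correction undercounts corners;
* the eggshell ellipsoid by algebraic least squares on the general
  quadric (smallest singular vector), with uniform weighting of the
  contour voxels, followed by eigendecomposition into center, semi-axes
  and orientation;
* 2D curve depth as the maximal perpendicular distance from the
  endpoint-to-endpoint chord of the mid-plane contact trace, signed
  positive toward P1 (the chord-to-apex convention); the mesh-based
  equivalent fits a plane to the triple line and reports the signed
  maximal deviation of the contact surface;
* contact-shape classification (curved iff the endpoint–midpoint–
  endpoint angle is strictly below 160 degrees), cell-size symmetry
  (AP lengths within 10%, inclusive, relative to the larger cell),
  cortical intensity normalization by the time average of the
  area-weighted merged-region mean, and kymograph velocimetry (mean
  least-squares slope of three path lines).

## Synthetic data

Because no imaging data are deposited with this kind of experiment, the
package generates everything it needs:

* embryo geometries: eggshell semi-axes 25 x 15 x 15 um jittered by
  ±10%, AB volume fraction uniform in 0.55–0.60 (AB is reproducibly the
  larger blastomere), and the two cells occupying 95% of the shell
  volume. The fraction range reflects the well-known AB>P1 size
  asymmetry; the packing fraction is an assumption — no measured cell or
  shell volumes are available to calibrate it;
* confocal-like stacks: membrane fluorescence placed on the equilibrium
  surfaces by area-weighted deterministic sampling, an eggshell channel
  on the ellipsoid surface, anisotropic Gaussian PSF blur, Poisson
  photon noise (photon scale 100 by default, i.e. peak SNR ~10) plus
  Gaussian read noise. Every generator is a pure function of its
  configuration and seed;
* kymographs (path lines at the true flow velocity, 100-ms frame
  interval, 0.3-um positional noise) and cortical intensity traces (an
  AB ramp reaching 1.25 at 8 minutes over a flat P1 level of 0.80, in
  normalized units), used to exercise the velocimetry and normalization
  operators end to end;
* an analytic equal-tension double bubble (spherical caps meeting at
  120 degrees) constructed independently of the minimizer, used to
  validate the simulator against closed-form geometry.

What the synthetic stacks do *not* emulate: optical artifacts
(depth-dependent attenuation, refraction at the eggshell), the doubled
membrane signal where two apposed membranes meet at the contact,
cytoplasmic autofluorescence, and any temporal dynamics. Passing the
closure tests therefore demonstrates that the pipeline stages compose
correctly and are unbiased under the stated noise model — not that
segmentation accuracy would be identical on real stacks.

## Design choices and limitations

* **Packing fraction dominates the confined equilibrium.** The free
  menisci between the cells and the shell set the reference pressures
  through Laplace's law, and the menisci's curvature is controlled by
  how much free volume the shell leaves: tighter packing squeezes the
  menisci into smaller radii, raises both reference pressures, and
  deepens the equilibrium contact under heterogeneous tensions. The
  default 0.95 is a stated assumption of the synthetic geometry — no
  measured cell or shell volumes exist to calibrate it — so
  heterogeneous-model contact depths on the synthetic geometry should
  be read as packing-dependent rather than as biological predictions.
  Users fitting real stacks are unaffected: there the volumes and shell
  come from the segmentation.
* **Depth measurement.** The triple-line plane fit and the mid-plane
  chord agree when the triple line is planar, which holds to ~0.03 um
  in the converged shapes; for strongly non-planar contact rings the
  two conventions would diverge.
* **Triple line on the shell.** Vertices shared by all three patches
  that also touch the shell are doubly constrained; projection onto the
  shell is applied first, then smoothing moves them only along the
  triple line.
* **Watershed boundary and overlap scores.** The watershed keeps a
  one-voxel boundary label, so for Dice comparisons against boundary-free
  ground truth the lines are filled by majority face-neighbour vote
  (`fillBoundary`).
* **Degenerate inputs.** Coplanar point sets are rejected by the
  ellipsoid fit; coincident markers by the watershed; collinear clouds
  by ICP; non-closed bodies by mesh validity. Tension sets violating the
  stability inequality are refused by the simulator and silently
  excluded from grids.
* **Problem sizes.** Tests run the confined equilibria at 5 632
  triangles (four subdivision rounds) and the acceptance computations at
  22 528 (five rounds); grid-search closure uses a 4 x 4 tension
  sub-grid around the generating point with three noise replicates.
  These sizes keep the full suite within minutes while staying inside
  the mesh-convergence regime established above.
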