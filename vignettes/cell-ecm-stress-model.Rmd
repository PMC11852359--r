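---
title: "Stress in tensegrity cells embedded in soft and stiff ECM: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress in tensegrity cells embedded in soft and stiff ECM: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the model answers

Epithelial cells growing in three-dimensional culture experience very
different mechanical environments depending on whether they rest in a stiff
hydrogel scaffold or float almost freely in medium. `cytofem` implements a
finite-element model of that contrast: one cell, or a group of 18 cells,
embedded in an elastic extracellular-matrix (ECM) block whose top surface
carries a small external pressure (6.0 Pa by default). The only quantity
varied between conditions is the ECM Young's modulus — 56,200 Pa ("stiff",
an alginate-like gel) versus 30 Pa ("soft", approximating medium) — and the
model asks how the stress experienced by each cellular component changes.

The robust, mesh-insensitive output is a set of *orderings* of maximum
Huber–Mises–Hencky (HMH, von Mises) stresses:

* ECM stress concentrates more around cells in the **stiff** gel;
* every intracellular component (cortex, cytoplasm, nucleus, nuclear
  membrane) carries higher maximum stress in the **soft** gel;
* a group of cells concentrates more ECM stress than a single cell;
* cytoskeletal uniaxial stress extremes and displacements are larger in the
  soft gel.

Absolute stress magnitudes depend strongly on the exact cell shape (real
cells are irregular; imaging-derived geometries vary from cell to cell)
and on the poorly constrained cytoskeletal prestress magnitude, so the
package treats them as indicative only; the orderings are the reproducible
science and are what the test suite asserts.

## Model components

Each cell consists of:

* **Nucleus** (linear tetrahedra, E = 400 Pa, nu = 0.37) of radius 5 um;
* **Cytoplasm** (tetrahedra, E = 100 Pa, nu = 0.37) filling the shell out
  to the cell radius of 10 um;
* **Cortex** and **nuclear membrane**: 3-node constant-strain membrane
  triangles in plane stress (no bending), E = 1000 Pa, nu = 0.3, thickness
  6 nm, closed surfaces at the cell and nucleus radii;
* **Cytoskeleton**: a six-strut tensegrity with 6 bars (microtubules,
  E = 1.2 GPa, cross-section 190e-18 m^2, no pre-tension) and 24 tendons
  (actin, E = 2.6 GPa, 18e-18 m^2, pre-tension force `tendon_prestress_n`).

The ECM is a nearly incompressible elastic continuum (nu = 0.4777) meshed
with the same tetrahedra. The model is continuous — cells and matrix share
interface nodes, so no contact conditions are needed. Boundary conditions
are rollers: the four side faces of the box are fixed in their normal
directions and the bottom in z, all tangential sliding free; the top face
carries the pressure as a consistent dead load along -z.

### The tensegrity form

The cytoskeleton graph is the icosahedral six-strut tensegrity: 12 nodes,
each touching exactly one bar and four tendons. For the geometry we place
the nodes on the *self-equilibrated* form of that structure — the vertex
family (0, ±1, ±c), (±1, ±c, 0), (±c, 0, ±1) with c = 1/2 (Jessen's
icosahedron) scaled to the cell radius — rather than the regular
icosahedron (c = golden ratio). The distinction matters: the regular form
admits a finite mechanism through which equal tendon pre-tension relaxes
completely, while the c = 1/2 form supports a self-stress state in which
tendon tension is balanced by bar compression at 1.5 times the tendon force
density. With the default pre-tension of 9e-13 N, a free-floating
cytoskeleton relaxes to tendon stresses of about +3.3e4 Pa and bar stresses
of about -7.7e3 Pa, reproducing the signature "tendons tensile, bars
compressive" state.

The 12 tensegrity nodes are snapped to the nearest cortex mesh nodes
(attachment by shared node, all 12 on the outer membrane). This choice puts the
cytoskeletal point loads on the outer membrane, which is where the model
develops its characteristic punctual cortical stress concentrations; an
alternative inner attachment to the nuclear membrane was considered and
left as a non-default option.

### Tendon prestress magnitude

Cytoskeletal pre-tension in living cells is poorly constrained. The
default, 9e-13 N, makes the tendon uniaxial prestress P/A = 5e4 Pa — the order of
magnitude of the cytoskeletal uniaxial stresses the model reports
(1e4–1e5 Pa). Because this is a guess, `analysis/03_prestress_sensitivity.R`
re-runs the whole comparison across a 10x range of the force
(2.85e-13 to 2.85e-12 N); every stiff-vs-soft and group-vs-single ordering
is unchanged across that range, which is also asserted by the test suite.

## Geometry and meshing

No constrained-Delaunay mesher is used. Instead the mesh is built from
structured hexahedral blocks (a "butterfly"/O-grid construction):

1. a uniform cube-surface grid with `n_face` divisions per face is
   projected onto the unit sphere, giving one shared surface topology;
2. a cube lattice fills the nucleus core; radial shells sweep core → nucleus
   sphere → cortex sphere → the cell's grid cube → (for groups) the ECM box;
3. every hexahedron is split into 12 tetrahedra around its centroid, with
   each quad face cut along the diagonal through its smallest global node
   id. Neighbouring hexes see the same global ids, so shared faces are
   always triangulated identically — the mesh is conforming by
   construction, including across cell-cube boundaries and at both
   membrane surfaces (whose triangles are exactly the shared tet faces).

This yields bit-deterministic meshes (two builds are `identical()`),
exact 90-degree rotational symmetry about z for spherical cells, and exact
node sharing for the cytoskeleton attachment, at the price of some element
shape quality near cube edges (minimum tet quality ~0.05, comfortably above
the 0.02 validation threshold). `validate_mesh()` checks orientation,
conformity (membrane triangles shared by the correct solid regions),
attachment, duplicate/orphan nodes and shape quality, and reports offending
element ids.

Cell shape is spherical by default. Real cells observed in confocal
stacks are irregular and flattened; `oblate_transform()` provides a
volume-preserving squashed variant, and any positive-determinant affine
transform is accepted as a crude stand-in for an imaging-derived shape.
Shape is the single largest driver of absolute stress magnitudes.

The 18-cell layout is two horizontal 3x3 layers on a regular grid with
25 um center spacing — a compact double-layer arrangement typical of small
printed or self-organised cell clusters — padded to the ECM box by a
mapped shell. Spacing, counts and the box padding are all configurable in
`scene_spec()`.

## Finite-element formulation

The kinematics are total-Lagrangian. For a displacement-gradient increment
the Green–Lagrange strain increment splits as `dE = de + deta` with
`de = sym(grad)` the linear part and `deta = 1/2 grad^T grad` the
quadratic part (`compute_strain_increment()` exposes exactly this split).
The constitutive law is isotropic St. Venant–Kirchhoff per component;
membranes use its plane-stress reduction; trusses carry Green strain with
an initial (prestress) stress. All tangents include the geometric
(initial-stress) stiffness, which is what lets the prestressed tensegrity
equilibrate stably.

Loading follows the two-step schedule: step 1 ramps tendon pre-tension
over 2 increments with no pressure; step 2 ramps the pressure over 6
increments on the prestressed state. Each increment is solved by
Newton–Raphson with a relative force-residual tolerance of 1e-8 and at
most 20 iterations. Two pragmatic convergence refinements are included:
a residual that stalls at the floating-point noise floor (below 1e-4 of
the reference but no longer decreasing) is accepted, as is an absolute
floor of 1e-9 of the overall applied-force scale — both only matter when
the increment's load is tiny compared to round-off accumulation. The
tangent systems are solved with CHOLMOD's supernodal Cholesky (AMD
ordering), falling back to sparse LU if the factorization fails.

### Numerical choices worth knowing about

* **Pressure as dead load.** The top pressure is converted to consistent
  nodal forces on the *undeformed* surface (p·area/3 per triangle node,
  along -z). At 6 Pa the geometry change is minute relative to the box, so
  follower-load effects are negligible.
* **No B-bar / mean dilatation.** The ECM's nu = 0.4777 invites volumetric
  locking with linear tetrahedra. Element-level mean dilatation is an
  identity for constant-strain tets, and nodal-averaged-Jacobian schemes
  would change the element contract, so the plain displacement formulation
  is used throughout. Locking mildly stiffens the ECM response at fixed
  mesh; it affects absolute magnitudes, not the orderings, which are
  verified to be stable across mesh resolutions.
* **Stress evaluation at element centroids.** Constant-strain elements
  make centroid values exact; no nodal extrapolation or averaging is done,
  because the reported quantities are maxima and averaging biases maxima
  low. Cauchy stress is reported (second Piola–Kirchhoff pushed forward).
* **Membrane HMH** uses the in-plane plane-stress tensor with out-of-plane
  components zero, consistent with membrane theory.
* **Patch-test regime.** The confined-compression closed form
  (sigma_z = -p, HMH = p(1-2nu)/(1-nu)) is the linear-elasticity solution.
  With finite-strain kinematics at p = 6 Pa the Cauchy stress deviates
  from it by O(strain) ≈ 2e-4 relative — a property of the continuum
  model, not the mesh. The patch test therefore runs in the infinitesimal
  regime (p = 1e-4 Pa), where both the incremental solution and the
  linearised solver mode reproduce the closed form to better than 1e-6 on
  arbitrarily jittered meshes.
* **Log-scale output.** VTU exports include a decimal-log HMH channel
  clamped below at a configurable floor (default 1e-12 Pa), matching the
  log-scale visualisations customary for these strongly localised fields.

## What the synthetic geometry does and does not emulate

The generator reproduces the *structure* of the physical system — nested
nucleus/cytoplasm/membranes, prestressed tensegrity attached to the
cortex, near-incompressible matrix, roller-bounded box under top pressure,
and the single-vs-18-cell layouts. It does not reproduce irregular
imaging-derived cell shapes, production-scale (multi-million-element)
meshes, or any cell-to-cell variability. Consequently, passing tests
demonstrate that the *mechanical mechanism* (stiffness-dependent stress
shielding and concentration) and its orderings are real and robust in
this model class — not that any particular experimental geometry's
absolute stress magnitudes are recovered.

## Problem sizes

The default "desk-scale" resolution targets ~1.8e4 tetrahedra for the
single cell (n_face 5, layers 2/3/4) and ~7.3e4 for the 18-cell group
(n_face 3, layers 1/2/2, two padding layers); the full 2x2 matrix solves
in a few minutes on one CPU. The test suite uses a coarser companion
resolution (~3.5e3 and ~1.9e4 tetrahedra) chosen so the entire ordering
matrix, the 10x prestress sweep and the two-resolution stability check
remain fast; the orderings are identical at both scales, consistent with
the observation that the field maxima are not strongly mesh-sensitive.

## Known limitations

* Linear tetrahedra with near-incompressible ECM overestimate ECM
  stiffness somewhat (no locking treatment, see above).
* Membranes have no bending stiffness; compressive membrane states that
  would wrinkle in reality are represented as in-plane compression.
* The prestress is force-controlled and applied only to tendons; the
  cortex is assumed initially unstressed (cortical tension is not
  modelled).
* Elasticity only: no viscoelasticity, poroelasticity, active
  contractility or remodelling; statics only.
* Embedded cytoskeleton members respond to matrix strain with their full
  axial stiffness, so in the stiff gel the pressure step can drive tendons
  into net compression; the free-standing prestress state and all |S11|
  orderings are unaffected.

## Reproducing the analyses

```{r, eval = FALSE}
# build + validate both geometries, export VTU
source("analysis/01_build_meshes.R")
# the 2x2 stiff/soft x single/group matrix with summary tables
source("analysis/02_run_matrix.R")
# ordering stability across a 10x tendon-prestress range
source("analysis/03_prestress_sensitivity.R")
```
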