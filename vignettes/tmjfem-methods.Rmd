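---
title: "Methods: image-based finite-element analysis of a TMJ prosthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based finite-element analysis of a TMJ prosthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tmjfem` rebuilds, as reusable and tested code, the simulation chain used
to analyse a custom temporomandibular-joint (TMJ) prosthesis from CT data:
calibration, segmentation, Hounsfield-unit-based material mapping,
quadratic tetrahedral meshing, linear-elastic solves with bonded and
frictional interfaces, normalized von Mises comparison across model
variants, and gravimetric wear-rate regression. This vignette records the
model assumptions, the tunable parameters, and the numerical and design
decisions, in the order the pipeline runs.

## The synthetic phantom: what it emulates, and what it does not

Patient CT volumes and manufacturer CAD cannot be redistributed, so every
stage operates on a seeded synthetic phantom (`build_phantom()`). The
phantom emulates the *structure* of the clinical inputs:

* a voxel grid of 120×120×90 at 0.3 mm isotropic spacing (the resolution
  class of a post-operative CT of the mandible), with raw values
  `raw = 0.8·HU + 1024` plus Gaussian noise (default σ = 30 HU) so the
  calibration stage has a genuine transform to invert;
* a horseshoe-shaped mandible body (a half-torus, major radius 10 mm,
  minor 3.2 mm) with a 1 mm cortical shell over a trabecular core, one
  intact condylar stub on the contralateral side, and a flat cortical
  "plate seat" slab on the resected side representing the lateral ramus
  surface the fixation plate sits on;
* four teeth (enamel caps over dentin), a titanium prosthesis plate with a
  condylar head, three fixation screws crossing the plate–bone interface,
  and two small "dummy" screw stubs that exist in the planning geometry
  only (rasterized into the volume only on request);
* nominal HU per tissue ordered air (−1000) < soft tissue (40) <
  trabecular (300) < cortical (1200) ≤ dentin (1700) < enamel (2400) <
  titanium (3000).

The geometry is parametric, not anatomical: validation is property-based
(exact recovery, conservation, closed forms), not geometry-matching.
Deliberately absent are CT physics (beam hardening, reconstruction
kernels, partial-volume averaging — the rasterization is nearest-neighbour
per voxel centre) and anatomical detail (muscle architecture, periodontal
ligament, condylar cartilage). Consequently a Dice of 1.0 on the noise-free
phantom shows the chain is *exact on its own terms*; it does not show that
real mandibular CT segments this cleanly, where partial-volume effects and
metal artifacts dominate. The optional `metal_artifacts` toggle adds
streak-like noise on slices intersecting titanium as a rough stress test
only.

Muscle forces are a placeholder table (bilateral masseter, temporalis and
pterygoid entries of 110–190 N directed superior-anteriorly, applied over
spherical attachment regions); users with a musculoskeletal simulation of
their own case should substitute its output. Muscles whose attachment
region falls on resected (absent) bone are dropped with a message,
mirroring the surgical situation.

## Calibration and segmentation

`calibrate()` applies the two-point linear map sending the mean raw value
of water to 0 HU and of air to −1000 HU. The phantom carries both
reference means in its truth record; for real data they are measured from
homogeneous regions.

Thresholding (`threshold_mask()`) supports a fixed range and an
Otsu-style adaptive split restricted to a bounding region; the vendor
tooling this stands in for does not publish its algorithm, so Otsu on a
256-bin histogram is the documented choice. Cleanup (`morph_clean()`)
applies island removal (drop 26-connected components below `min_island`
voxels), cavity fill (fill 6-connected background components not reaching
the volume border — the standard dual connectivity pair), and closing with
a spherical element. Closing can enclose new cavities, so the sequence is
iterated to a fixed point, making the operation idempotent. Overlaps
between masks are resolved by list order (`resolve_priority()`), with the
default priority prosthesis > screws > teeth > mandible.

Surface extraction (`extract_surface()`) emits the 0.5-level isosurface of
the binary field under nearest-neighbour interpolation — voxel faces split
into oriented triangles. This is deliberately *not* smoothed: the jagged
voxel surface is part of what distinguishes a segmented implant model from
its CAD counterpart, and the enclosed volume equals the voxelized volume
exactly, which the tests exploit. Gaussian surface smoothing
(`smooth_surface()`, σ in voxels) exists but defaults off for screw-bearing
masks: a structure one voxel thick erodes or vanishes under σ = 1.5.

"Manual" CAD-to-segmentation alignment is an explicit rigid transform
(reproducibility over interactivity); `align_surface(refine = "on")` runs
point-to-surface ICP with a Kabsch update and never returns a transform
with a larger mean closest-point distance than its start. Deviation maps
(`surface_deviation()`) are unsigned point-to-triangle distances from the
reference vertices — unsigned because the comparison of interest
("distances mostly below 1 mm") does not need a sign convention — and the
summary reports max, mean and the fraction below 1 mm.

## Material mapping

The mapping table ships as a versioned JSON asset (`material_table()`):

| regime / tissue | CT (HU) | ρ (kg/m³) | E (MPa) | ν |
|---|---|---|---|---|
| trabecular bone | −1000–500 | 0 ≤ ρ < 1000 | 0.0004·ρ^2.01 | 0.30 |
| cortical bone | 501–1500 | 1001 ≤ ρ < 2000 | 0.005·ρ^2.01 | 0.30 |
| dentin | ≤ 2000 | — | 24 535 | 0.30 |
| enamel | > 2000 | — | 39 605 | 0.30 |
| Ti-6Al-4V | — | — | 113 800 | 0.342 |
| uniform bone | — | — | 10 000 | 0.30 |

Three numerical decisions deserve a note:

* The printed intervals leave gaps (HU 500→501, ρ 1000→1001) and the two
  power laws disagree where they meet, jumping from ≈428 MPa at ρ = 999 to
  ≈5358 MPa at ρ = 1000. The laws are implemented exactly as printed, with
  ρ ∈ [1000, 1001) assigned to the cortical law; the discontinuity is a
  property of the source table and is not smoothed. The table's printed E
  ranges (180–380 and 11 300–22 900 MPa) are inconsistent with evaluating
  the laws at the printed ρ endpoints; they are carried as metadata only.
* HU outside [−1000, 1500] in a bone mask clamp to the density floor and
  ceiling; nothing else is defined there.
* A modulus floor of 0.01 MPa keeps stiffness matrices positive definite
  for elements whose density maps to (near) zero.

Per-element HU is the mean of trilinear samples at the element's four
quadrature points — the locations where stiffness is integrated — with a
centroid-sampling alternative by configuration. Tooth elements are
classified dentin/enamel per element by the 2000 HU rule (inclusive below).

## Meshing

`mesh_from_labels()` converts a label volume to conforming C3D10 elements:
optional integer downsampling (the stand-in for the vendor "coarseness"
control), a translation-invariant 6-tetrahedron (Kuhn) split of each voxel
— chosen over the 5-tet split because face diagonals then match across
neighbours without parity bookkeeping — and promotion to quadratic by
edge-midpoint insertion. Nodes are deduplicated on the exact
double-resolution integer lattice, avoiding floating-point hash fragility;
interfaces between parts therefore share nodes. Mid-edge nodes sit at
exact midpoints ("straight edges"), so every element's geometry map is
affine — which the assembly exploits (one constant Jacobian per element)
and which makes the element volumes sum to the voxel volume exactly.

Downsampling takes the majority label per block, except that labels listed
in `preserve` (thin metal parts) win a block on their own count whenever
they occupy at least 25% of it; each preserved label competes with its own
count only, so adding one preserved part (the dummy screws) never changes
how the others downsample — Model 3 minus its dummy-screw elements is
Model 2's mesh exactly.

## Solver

Units are fixed at mm–N–MPa (densities enter only the material law, in
kg/m³ as printed). Stiffness uses the standard isoparametric formulation
with the 4-point Gauss rule; assembly is vectorized over elements via the
isotropic block identity
K_ab = ∫ λ g_a g_bᵀ + μ g_b g_aᵀ + μ (g_a·g_b) I. Dirichlet data is
applied by elimination (supporting prescribed affine fields for patch
tests); the sparse symmetric system is solved by direct factorization
(`Matrix`/CHOLMOD), and every solve verifies the relative equilibrium
residual (tolerance 1e-8).

Concentrated loads split equally over node sets; surface loads lump per
facet by area. Within a facet, two schemes exist: the default spreads a
facet's share equally over its corners, while the `"consistent"` scheme
uses the consistent nodal loads of a uniform traction on a straight-edge
quadratic facet — zero at corners, one third per mid-edge node — which
load cases use by default when facet mid-nodes are known. The distinction
matters: equal lumping perturbs the stress field near the loaded face,
while consistent lumping makes uniform-stress states exact to round-off,
which the closed-form bar comparisons require.

Bonded interfaces: conforming parts already share nodes (no equations);
non-conforming ties interpolate each slave boundary node at its closest
point on a master facet with quadratic 6-node weights, eliminated through
a transformation matrix. A tied assembly moves rigidly without constraint
violation, and a non-conforming two-block column under uniform compression
reproduces the merged-column stress exactly (the fine quadratic trace
space reproduces the coarse one).

Contact ("hard contact" surrogate): the conforming interface is detached
(`split_interface()`), duplicating nodes shared exclusively by the two
parts — nodes also touched by screws stay shared, keeping the screws
bonded. The named surface-to-surface scheme is approximated by
node-to-surface penalty contact that degenerates to coincident node pairs
on voxel interfaces. Each pair is weighted by its consistent tributary
area (zero at facet corners, one third of the facet area per mid-edge
node): springs of equal stiffness cannot transmit a uniform pressure on
quadratic facets, weighted ones reproduce it exactly. Penalty stiffness
defaults to 50·max(E)/h per unit area (h the mean element edge), escalated
tenfold (up to three times) if penetration exceeds 1e-3·h. Friction is
Coulomb with μ = 0.3 by default, solved by an active-set iteration with
radial-return slip updates and Anderson-accelerated mixing of the slip
history (the fixed point is affine for a frozen partition, so mixing
converges in a handful of iterations where plain substitution stalls).
Convergence requires a stable open/stick/slip partition — ignoring pairs
whose force is below 1e-3 of the contact-force scale, which otherwise
chatter indefinitely on coarse interfaces — plus stagnant contact forces,
or a bounded Coulomb violation together with a stagnant displacement
field. A tangential load exceeding the friction capacity of a statically
loaded interface has no equilibrium; the solver then reports
non-convergence with its last residual rather than a silent answer.

## Post-processing and the variant ladder

Von Mises stress is evaluated at quadrature points and peaks are taken
there, not at nodal extrapolations, which inflate maxima mesh-dependently.
The proprietary material limit used for normalization in the industrial
setting is replaced by a user-supplied reference; `run_all()` uses the
industrial-style run's own peak, so its normalized value is 1 by
construction and the other variants are read relative to it.

The ladder: Model 1 (everything segmented), Model 2 (CAD prosthesis and
screws), Model 3 (plus dummy screws), Model 4 (CAD + dummy screws, teeth
merged into uniform 10 GPa bone, coarseness 6, contact configurable), and
the industrial-style run (as Model 4's simplification but at the fine
coarseness 3, interface detached and not considered). Default mesh
coarseness is 3 for the fine models — about 20 000 nodes, solving in tens
of seconds — and 6 for Model 4, giving the ≥5× node reduction that mirrors
the simplified-model regime; these sizes keep a full `run_all()` in a few
minutes on one CPU. On the phantom, exact segmentation makes Models 1 and
2 identical (real data would differ through segmentation artifacts); the
informative comparisons are the dummy-screw effect (< 2%) and the contact
effect (the frictional variant's peak is below the free-interface
variant's, the direction reported for such comparisons).

## Wear analysis

`wear_rate()` fits W(n) = a·n + b by ordinary least squares to the
soak-corrected net mass loss (`net_mass_loss()` adds the soak-control gain
to the specimen loss, removing common environmental drift), reporting a
per 10⁶ cycles plus per-500 000-cycle interval rates. The full
soak-control protocol of the standard is reduced to this additive
correction — only the linear model with constant b is specified by the
source material. Volumetric rates divide by density: UHMWPE at 0.93 mg/mm³
(not printed in the source; configurable and logged) and Ti-6Al-4V at
4.43 mg/mm³. The cyclic-test kinematics (12° rotation, 8.5 mm
anterior/posterior and 0.7 mm medial/lateral translation at 20 N over
5 million cycles) are scenario metadata (`wear_scenario()`); no
tribological model is simulated. The 70/30 ipsilateral/contralateral split
of the static compression test is `compression_load_split()`.

## Known limitations

* Linear elasticity, small strain, no dynamics or plasticity; screw
  threads are idealized as bonded (valid for global load transfer, not for
  local thread stresses).
* Node-pair penalty contact is a desk-scale surrogate for a mortar or
  Lagrange scheme; contact pressures on coarse voxel interfaces are
  resolved only to the facet scale.
* The bone material laws are generic, not mandible-specific — a recognized
  gap in the field; anisotropy and viscoelasticity are out of scope.
* The phantom's passing grades bound the implementation's correctness, not
  the clinical accuracy of any real-data analysis.
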