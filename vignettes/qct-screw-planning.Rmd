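---
title: "QCT-based finite-element screw planning and drill-guide auditing: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QCT-based finite-element screw planning and drill-guide auditing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Revision fixation at the first sacral level is hard when a broken screw
fragment is retained in the bone: the surgeon must place a new pedicle screw
along a corridor that avoids the fragment, in bone whose quality varies
enormously between the sacral body and the ala. `sacronav` implements an
open, fully scriptable version of the workflow that supports such a case:

1. calibrate the CT scanner's Hounsfield scale against an in-scan density
   phantom,
2. build a patient-specific, heterogeneous linear-elastic finite-element
   model of the bone with a virtually inserted screw,
3. compare the pull-out stiffness of candidate trajectories,
4. generate a drill-guide template that materialises the chosen plan, and
5. audit realized drilling against the plan on a post-drill CT.

No clinical data ships with the package. A synthetic phantom generator
produces QCT-like volumes with exactly known ground truth, so every stage is
testable end to end.

# Material model

## HU to apparent density

The scanner's HU scale is calibrated by regressing known rod densities of an
in-line phantom (five rods, default equivalent BMD 0, 0.05, 0.10, 0.15,
0.20 g/cm³) on their measured mean HU:

\[ \rho_{app} = a + b \cdot HU . \]

`fit_hu_to_density()` is an ordinary least-squares fit; rod means are taken
over rod interiors eroded by one voxel so partial-volume boundary voxels do
not bias them. The packaged default law, used by the synthetic generator, is
\(\rho_{app} = -0.0829 + 0.0026\,HU\) (g/cm³). On a noiseless phantom the
fit returns the generating coefficients to ten significant digits; with
noise it equals the closed-form normal-equation solution by construction.

## Density to elastic modulus

Bone is isotropic linear elastic with \(\nu = 0.3\) and a trabecular-type
density–modulus law

\[ E = -34.7 + 3230\, \rho_{app} \quad \text{(MPa)} . \]

The law crosses zero near \(\rho_{app} \approx 0.0107\) g/cm³; elements
below that are clamped to `e_min` (default 0.01 MPa) to keep the global
stiffness matrix positive definite. Clamping is flagged per element in the
material report. Implant parts (screws, retained fragment) are assigned
E = 114 000 MPa, ν = 0.3 regardless of image content; image voxels at or
above the metal threshold (default 2000 HU) are excluded from bone element
means so a neighbouring implant cannot inflate bone stiffness — the same
exclusion is applied to the centroid-interpolation fallback.

Per-element HU is the mean over CT voxels whose centres fall inside the
element (`sampling = "mean"`, the default); elements that contain no voxel
centre fall back to trilinear interpolation at the element centroid. The
alternative `"centroid"` strategy is exposed because the right choice is not
obvious a priori; on the phantoms the two differ by far less than the
between-trajectory differences of interest.

# Geometry pipeline

`segment()` applies an HU window, keeps the largest 26-connected component
and fills internal holes slice-by-slice in 2D while preserving the outer
contour — so a cortical shell encloses a homogeneously filled mask even when
the trabecular interior falls below the threshold. Default thresholds (bone
≥ 200 HU, metal ≥ 2000 HU) are configuration values, not claims about any
scanner.

`extract_surface()` contours the mask by marching tetrahedra: each lattice
cell is split into the six Kuhn tetrahedra sharing the main diagonal, which
makes the triangulation consistent across cells and the output watertight by
construction. The binary mask is first box-filtered (3³ kernel, one pass by
default) so the 0.5-level set follows the partial-volume boundary rather
than the voxel staircase; on a digital sphere at 0.6 mm voxels this brings
surface area within a fraction of a percent of \(4\pi r^2\).

`smooth_surface()` is λ/µ (Taubin-style) smoothing: a positive Laplacian
step with weight `factor` followed by a negative step
µ = −factor/(1 − 0.1·factor) that re-inflates the surface. At the default
six iterations with factor 0.7 the enclosed volume of a sphere changes by
well under 1 %, which is what "shrinkage compensation" has to deliver.

`remesh_uniform()` is incremental isotropic remeshing (split edges > 4/3 of
the target, collapse edges < 4/5 with manifold link-condition guards,
tangential relaxation with projection back onto the input surface). Edges
whose dihedral normal deviation exceeds `sharp_angle_deg` (default 60°) are
constraint edges: crease vertices move only along the crease and corner
vertices are pinned, so a cube remeshed at 0.6 mm keeps its edges to within
numerical precision. The median output edge stays within 25 % of the
target.

`make_screw()` builds the screw as a watertight solid of revolution: a
45 × 6.5 mm smooth shaft, a neck, and a cylindrical monoaxial head. The
thread profile is decorative only — the analysis geometry is the smooth
shaft, consistent with the fully tied interface idealisation. The head sits
proud of the bone on a neck stand-off so that load is introduced through
the screw, not through spurious head–cortex contact.

# Finite-element model

## Meshing

No tetrahedral meshing library is available to build on, so
`tetrahedralize()` is a structured voxel-grid mesher, the standard approach
of image-based bone FE: a uniform node lattice at the requested element
size covers the assembly, each cell is split into six tetrahedra, and each
tetrahedron is labelled bone / fragment / screw by point-in-solid tests of
its centroid against the assembly surfaces. Elements are straight-edged
10-node tetrahedra (midside nodes at edge midpoints).

Two consequences of this choice are worth stating plainly:

* The bone–implant "tie" is realized by merged interface nodes — embedded
  implant elements share lattice nodes with adjacent bone elements, which
  is kinematically a tie for matched meshes. Implant elements whose
  centroid lies *outside* the bone (the proud neck, head, and a bicortical
  tip) are detached: nodes they would share with bone are duplicated, so
  staircase adjacency cannot weld parts that are not in contact.
* The mesh is single-resolution. The element-size argument sets the lattice
  pitch; there is no separately refined interface band. Mesh-convergence
  studies therefore vary one global size, which preserves the semantics of
  the nine-size refinement protocol (element counts grow monotonically as
  the size shrinks).

## Solving

`solve_static()` assembles the isoparametric tet10 stiffness with a 4-point
Gauss rule in compiled code, distributes the total load equally over the
head-load nodes, eliminates fixed degrees of freedom and solves the sparse
SPD system with a Cholesky factorisation. The solver is verified against
closed forms: a uniaxial bar reproduces \(FL/EA\) to machine precision
(with consistent face tractions via `consistent_face_load()`), a slender
cantilever matches \(FL^3/3EI\) within a few tenths of a percent, global
reaction forces balance the applied load to 1e-13 relative, and the
assembled matrix agrees with a dense direct-assembly oracle.

The load case is a 500 N tensile force along the outward screw axis. The
bone is fixed on the superior endplate patch and on the caudal third of its
axial extent. The pull-out stiffness is

\[ k = F / \bar u_{head} , \]

with \(\bar u_{head}\) the mean displacement magnitude over the nodes of
the middle third of the screw head.

# The synthetic phantom

`phantom_spec()` describes the whole scene; `generate_phantom()` renders it
with 2× per-axis supersampling (partial-volume boundaries) plus Gaussian
HU noise (default sd 15 HU), and returns the full generating truth:
analytic surfaces, corridor axes, registration landmarks, the density
field, and the rod geometry.

The bone stand-in is a two-ellipsoid solid: a "body" (semi-axes
26 × 18 × 15 mm) and an "ala" wing (30 × 13 × 7.5 mm, placed cranially and
laterally), with a 2 mm cortical shell of apparent density 1.5 g/cm³.
Trabecular density in the body rises toward the superior endplate
(0.12–0.22 g/cm³, subchondral densification); the ala interior is
marrow-like at 0.03 g/cm³. These are the two documented features of sacral
bone-quality distribution that make a convergent bicortical corridor
mechanically superior to a divergent alar one, and they are what the
default phantom is built to emulate. A retained broken-screw fragment
(4 × 14 mm cylinder at saturated metal HU) sits caudal to both corridors;
the default plans clear it by 6.8 mm (S1) and 11 mm (ALA), which
`check_collision()` verifies.

The two default trajectories are computed against the analytic surface:

* **S1 (convergent, bicortical)** — enters the posterior body and crosses
  the contralateral cortex; about 43 mm of the 45 mm shaft is buried and
  the axis crosses the cortical surface twice.
* **ALA (divergent, monocortical)** — enters the dorsolateral ala surface
  and runs almost entirely inside the marrow-soft wing; the full shaft is
  buried with a single cortical crossing.

On this phantom, at the default 3 mm element size, the convergent corridor
is consistently stiffer than the divergent one (ratio ≈ 1.2, stable across
noise seeds). The margin is deliberately not tuned to match any particular
clinical number — it emerges from the density contrast and the bicortical
anchorage. Two limitations are documented rather than hidden: (i) at
element sizes ≳ 4 mm the 2 mm cortical shell is under-resolved by the
voxel mesher and the comparison becomes unreliable (this is precisely why
mesh-convergence studies at finer sizes exist); and (ii) oblique screw
entry makes the neck/head region genuinely interpenetrate the sloped
cortex, which a tied model turns into extra grip — the proud-head screw
geometry keeps this effect small.

What passing tests on this phantom do *not* show: realistic CT physics
(beam hardening, metal artefacts), anatomical shape fidelity, nonlinear or
anisotropic bone behaviour, interface micromotion or failure. The phantom
validates the *pipeline machinery* — calibration, mapping, meshing,
solving, registration, measurement — not patient-specific predictions.

# Drill guide

`extract_contact_patch()` selects the dorsal/cranial bone surface by face
normal direction and a spatial window; `build_guide()` constructs the
template implicitly — an offset shell of the (lightly smoothed) patch
unioned with a hollow tube per trajectory, minus the open drill channels —
and contours it with marching tetrahedra into a watertight printable STL.
By construction the tube axes coincide with the planned axes; on a flat
test patch the axis recovered from the contoured channel wall agrees with
the plan within 0.1°. On image-derived patches the contoured solid can
carry small topological handles from surface roughness; the mesh is still
watertight and the channels still coaxial, and the genus is reported
rather than asserted.

`compare_cast_to_pattern()` is the part-comparison instrument: per-vertex
signed distances (sign from the target's outward normals), summarised and
additionally clipped to ±1 mm for rendering parity with part-comparison
colour maps.

# Accuracy audit

`simulate_postdrill_volume()` renders the printed-model scenario: the bone
solid at plastic-like HU with metal drill bits (default ⌀2.5 mm) along the
realized axes, the whole scene moved by an arbitrary rigid pose.
`evaluate_drilling()` then:

1. segments the bits (metal threshold) and fits each axis by total least
   squares (principal direction; the fitted radius is sanity-checked
   against the nominal bit diameter),
2. reconstructs the model surface and registers it back to the plan —
   closed-form landmark Procrustes (`landmark_register()`, reflections
   excluded) followed by trimmed point-to-plane ICP (`refine_register()`,
   90 % trimming, 50 iterations max),
3. matches bits to plans by angle plus entry proximity, and reports per
   trajectory the 3D line-to-line angle
   \(\alpha = \arccos |a \cdot b|\), the entry offset, the breach distance
   against the safe corridor, and the Gertzbein–Robbins grade
   (A: 0, B: (0,2], C: (2,4], D: (4,6], E: > 6 mm breach).

The safe corridor defaults to a cylinder around the planned axis of radius
screw-radius + 4 mm; the grading bands are the scale's standard 2 mm
steps. On synthetic scenes the instrument recovers constructed tilts of
4.42° and 2.4° to within ~0.05°, is invariant to rigid scene motion well
within 0.2°, and reports grade A for tilts of this size — the same
qualitative outcome the workflow is designed to verify.

# Numerical choices and problem sizes

* Sparse direct (Cholesky) solve; typical demonstration models are
  5–12 × 10³ tet10 elements (30–80 × 10³ dof).
* Convergence tolerance: 2 % relative change of mean head displacement
  between consecutive refinements; the protocol runs the nine element
  sizes 2.0–6.0 mm (step 0.5).
* The packaged demonstration runs the nine-size protocol on a
  geometrically reduced phantom (scale 0.7, 0.8 mm voxels) and the
  trajectory comparison on the full-size phantom at 3 mm elements; both
  sizes were chosen once as a sensible demonstration budget for a desktop
  machine.
* All randomness (HU noise, demo poses) flows from one integer seed;
  per-stage sub-seeds are derived deterministically, and a rerun with the
  same configuration reproduces the summary bit for bit.

# Known limitations

* Linear elasticity with fully tied interfaces: no contact, friction,
  plasticity or pull-out failure; stiffness comparisons, not strength
  predictions.
* The voxel mesher's staircase boundaries converge in energy but make
  individual coarse-mesh stiffness values mesh-size dependent; compare
  trajectories at equal element size only, ideally ≤ 3 mm.
* The phantom is a stand-in, not an atlas shape; absolute stiffness values
  are not comparable to patient-specific numbers.
* Registration landmarks in the synthetic bench are exact; real landmark
  digitisation error would propagate into the angle measurement roughly
  linearly (the ICP stage absorbs small initial errors).
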