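---
title: "Designing mouth-opening tongue-depressing oral stents: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing mouth-opening tongue-depressing oral stents: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The clinical problem

Radiation therapy for head and neck cancer exposes healthy oral tissue to
dose it does not need to receive. A mouth-opening, tongue-depressing (MOTD)
stent fixes the jaw at a reproducible opening and pushes the tongue out of
the treatment field, sparing mucosa and improving setup reproducibility.
Such stents can be 3D printed from intraoral scans, but designing them in
general-purpose CAD is slow and operator-dependent. `stentforge`
implements a deterministic, semi-automated design workflow: two articulated
arch meshes plus a small set of dental landmarks go in, a printable
watertight stent comes out, with every design rule expressed as a number in
one configuration object.

## The nine-step workflow

All geometry lives in millimetres in a fixed anatomical frame: +Z is
occlusal/superior, +Y anterior, +X patient-left; "vertical" planes contain
the Z direction and "posterior" is $-Y$. The workflow is:

1. **Setup.** Validate landmarks, repair both arch meshes to watertight
   solids, and verify the articulated interincisal opening equals the
   configured 20 mm within 0.5 mm. The articulation is the scale reference:
   STL carries no units, so a wrong opening means a wrong scan or wrong
   units, and the step fails loudly rather than rescaling.
2. **Outline block.** Fit each arch's occlusal plane by PCA (the normal is
   the least-variance direction of the arch vertices, signed towards +Z).
   The maxillary plane is positioned at 60 % of the arch's height, the
   mandibular at 40 %, where height is the Z-extent from the gum-baseline
   landmark (the gum end of the scanned model) to the arch's occlusal
   extreme. Build the combined convex hull of both arches, expand it
   outward by 1.5 %, slice it at both planes, and Boolean-subtract the
   dentition. The result is the stent outline carrying a negative dental
   impression.
3. **Separation.** Split the block with a plane parallel to the mandibular
   plane, 2 mm above the lower central incisor tip.
4. **Third-molar trim.** Where a lower third-molar landmark exists, cut the
   lower stent with a vertical plane 1 mm distal of the second molar
   (the margin is this package's choice; only the removal itself is part
   of the design rules).
5. **Upper supports.** Carve each side's support from the upper stent with
   three vertical planes: mesial of the canine, distal of the second molar,
   and a parasagittal plane 5 mm lingual of the tooth row. This realises
   the stated tooth span (canine, both premolars, first two molars) with a
   concrete plane construction; the mesial/distal planes sit 4 mm outside
   the respective landmark so the whole crown is included. Without tooth
   landmarks the step falls back to arch-fraction planes and warns.
6. **Tail.** Union a box onto the lower stent spanning the plate's
   thickness band and reaching 10 mm beyond the lower second molar
   posteriorly (for edentulous arches: beyond the posterior ridge end).
7. **Tongue depression.** Subtract an ellipsoidal tongue body. The
   auto-placement puts its centre at the lower-teeth centroid translated
   17.5 mm posteriorly (laterally: the dental midline, i.e. the mean of
   left/right paired tooth midpoints, which is robust to asymmetric
   missing teeth); sizes it laterally at 0.8 times the inter-first-molar
   half-width, anteroposteriorly at 1.25 times that, vertically with an
   8 mm semi-axis; and sinks it so the dome apex sits
   `min_plate_thickness + 1` mm below the separation plane. The vertical
   rule is the published placement criterion itself — the mesh is placed
   *such that* the plate stays thicker than 10 mm — rather than a free
   parameter. The achieved minimum plate thickness is then measured by
   vertical ray casting over the depression footprint (0.5 mm grid) and a
   violation of the floor is an error, not a warning.
8. **Combine.** The upper supports live strictly above the separation
   plane (and on opposite sides of the midline); the lower stent strictly
   below. Their interiors are disjoint by construction, so the exact
   Boolean union is the concatenation of their boundaries and the combined
   volume is exactly the sum of the parts. This sidesteps the classic
   robustness failure of mesh Booleans across exactly coincident coplanar
   interfaces.
9. **Smoothing.** Taubin smoothing ($\lambda = 0.5$, $\mu = -0.53$, 10
   iterations) with every vertex within 0.5 mm of either arch surface
   frozen bit-for-bit, so the dental impression is untouched. The
   $\lambda/\mu$ pair makes the filter near-volume-preserving (within 3 %
   on the assembled stent).

Each step writes a binary STL checkpoint (`NN_stepname.stl`). Checkpoint
files are float32 by format; they are snapped and re-cleaned before
writing so the file on disk is itself watertight.

```{r}
library(stentforge)
anatomy <- generate_anatomy("normal", seed = 42)
design <- design_stent(anatomy, stent_config())
summary(design)
```

## The geometry engine

No mesh-Boolean, convex-hull or STL machinery suitable for this pipeline
exists in the R ecosystem available to the package, and robust Booleans
are the substance of the workflow, so the package carries its own compiled
engine:

* **CSG** uses a BSP-tree algorithm: both operands become binary space
  partition trees and are clipped against each other; coplanar faces are
  routed by normal agreement. Splitting is exact per plane, so identities
  such as $V(A \cup B) + V(A \cap B) = V(A) + V(B)$ hold to floating-point
  precision (the test suite asserts $10^{-6}$ relative over 50 seeded
  random cube pairs). The raw output has T-junctions along the
  intersection curve; a stitching pass splits only crack (unbalanced)
  edges at on-edge vertices and re-fans the affected faces, then residual
  hairline loops are closed like scan holes. If the result still is not
  closed, the operation falls back to voxel remeshing at 256 voxels along
  the longest axis with a warning — robustness is a requirement, and an
  approximate watertight answer beats an exact broken one. In the default
  test conditions the fallback never triggers.
* **Plane cuts** are Boolean subtractions against a large half-space box
  (side 10 times the mesh bounding diagonal, one face on the cutting
  plane), which caps the cross-section by construction. A plane that
  misses the mesh returns the input unchanged with a warning.
* **The convex hull** is a quickhull implementation; "expanded by 1.5 %"
  is implemented as uniform scaling by 1.015 about the hull's volume
  centroid, making the expansion exactly measurable (volume grows by
  $1.015^3$). A per-vertex normal-offset mode exists behind
  `expansion_mode = "normal_offset"` for sensitivity work; the isotropic
  reading is the default because it is the simplest consistent with a
  convex hull.
* **Volumes** use the divergence theorem (signed tetrahedra). The
  independent cross-check is a voxel oracle: vertical parity rays on a
  grid of columns with exact integration of inside intervals along Z.
  The two share no code path, and the suite requires 2 % agreement at 192
  columns per axis on every pipeline-scale solid.
* **Watertightness** means every directed edge is balanced by its
  reverse; `strict = TRUE` additionally requires 2-manifoldness. Repair
  welds duplicate vertices (rounding to $10^{-6}$ mm, never moving
  coordinates), drops degenerate triangles, ear-clips each boundary loop
  against its best-fit plane, and restores outward orientation by making
  signed volume positive per component. Inputs with more than 5 % boundary
  edges are refused as scan failures rather than patched.

## The synthetic anatomy generator

Real intraoral scans are patient data; the generator replaces them with a
deterministic parametric stand-in that exercises every code path. Each
arch is a single closed height-field solid: a band swept along a parabolic
arch curve (55 mm wide, 45 mm deep by default) whose top surface carries a
rounded gum ridge (12 mm) plus superellipsoid-profile tooth cusps (8 mm
nominal crown height) at up to 16 stations placed by arc length using
adult mesiodistal crown widths. Because the solid is a height field with a
flat base and rim walls, it is watertight by construction and needs no
Booleans; tooth-apex landmarks are exact surface vertices. Coordinates are
snapped to float32 so models survive STL checkpointing bit for bit.

Presets span the anatomy spectrum the workflow must tolerate: `normal`
(14 stations per arch; third molars can be enabled to exercise the trim
step), `hypodontia` (a seeded choice of 3 stations removed per arch from
the 10 candidates most often congenitally missing), `edentulous`
(ridge only; the ridge is 6 mm taller than the dentate gum base, as
scanned edentulous models retain the full alveolar ridge — without that
height no geometry can satisfy a 10 mm plate under a 20 mm opening), and
`class3` (mandible advanced 6 mm anteriorly). Seeded jitter
(uniform, 0.2 mm) perturbs tooth heights and stations; it is applied
before landmarks are derived, so landmark/mesh consistency holds for any
seed, and at zero jitter the normal arch is mirror-symmetric to $10^{-9}$.

What the generator does *not* emulate: real crown morphology (cusps,
fissures), soft tissue, scan noise beyond punchable holes, malocclusions
other than a rigid class III advancement, and arch asymmetry beyond
jitter. Passing tests therefore demonstrate that the *workflow logic* is
correct and deterministic on anatomically plausible geometry, not that
the landmarks or impression would fit a particular patient.

## Numerical choices and degenerate inputs

* CSG classification tolerance $10^{-5}$ mm; weld rounding $10^{-6}$ mm;
  T-junction stitch tolerance $10^{-5}$ mm. All well below the 0.1 mm
  slice thickness of the target printing process.
* Ray grids (thickness measurement, voxel oracle) are sheared by a fixed
  sub-spacing offset so rays never pass exactly through mesh edges;
  results stay deterministic.
* The tongue ellipsoid is an icosphere at subdivision 4 (5120 faces),
  whose volume is within 0.25 % of the exact ellipsoid; one level coarser
  misses by 0.9 %, more than the accuracy the suite demands of it.
* Degenerate inputs fail early with named errors: missing landmarks, a
  wrong interincisal opening (reported to 0.01 mm), collinear point sets
  in the plane fit, coplanar point sets in the hull, non-watertight
  Boolean operands, a separation plane that misses the block, and a plate
  thickness below the floor (reported with the measured value).
* There is no randomness anywhere in steps 1–9; two runs of the same
  anatomy and configuration agree in volume to $10^{-9}$ relative — the
  workflow-level analogue of reducing inter-user variability, taken to
  its limit.

## Problem sizes

Default fixtures put roughly 10k triangles on each arch; the outline block
carries ~90k after the impression subtraction and the assembled stent
a few hundred thousand faces before checkpoint cleaning. A full nine-step design takes well
under a minute on one CPU; the test suite's handful of full designs and
the geometry oracle suite together stay within a few minutes. These sizes
were chosen to resolve 0.2 mm jitter and 2 mm scan holes comfortably while
keeping Boolean trees shallow; they are configuration, not limits.

## Known limitations

* Tooth identification is landmark-driven by design; there is no automatic
  tooth segmentation. Landmarks come from the generator or from a JSON
  sidecar prepared for real scans.
* The BSP engine's worst case is quadratic in fragments; pathological
  meshes (millions of mutually slicing faces) should be decimated upstream.
* The combined stent is reported as (typically) three connected components
  that meet exactly at the separation plane; printing software treats the
  parts as one object, but a user expecting a single fused component
  should be aware the fusion happens at a measure-zero interface.
* Interactive adjustment of planes and the tongue body — part of the
  original semi-automated concept — is exposed only as configuration
  overrides (`stent_config()`, `tongue_params()`), not as a GUI.
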