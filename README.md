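# stentforge

Deterministic, semi-automated design of **mouth-opening, tongue-depressing
(MOTD) oral radiation stents** from articulated dental surface meshes.

Patients irradiated for head and neck cancer benefit from a device that
holds the jaw open at a reproducible height and presses the tongue out of
the treatment field: it spares healthy mucosa and makes daily setup
repeatable. Such stents can be 3D printed from intraoral scans, but
designing them by hand in general-purpose CAD is slow and
operator-dependent. `stentforge` turns a pair of watertight maxilla and
mandible meshes (millimetre STL, articulated at a 20 mm interincisal
opening) plus a small set of dental landmarks into a printable stent
through a fixed nine-step workflow — every design rule is a number in one
configuration object, and two runs on the same input agree in volume to
1 part in 10⁹.

The workflow, with the default design rules:

1. validate landmarks and the 20 mm articulation; repair meshes watertight;
2. fit each arch's occlusal plane by PCA (maxillary plane at 60 % of arch
   height from the gums, mandibular at 40 %), build the combined convex
   hull of both arches expanded outward by 1.5 %, slice it at those
   planes, and subtract the dentition — a stent outline carrying a carved
   dental impression;
3. split it 2 mm above the lower central incisor tip, parallel to the
   mandibular plane;
4. trim third molars from the lower stent (when landmarks say they exist);
5. carve left and right upper supports spanning canine → second molar with
   three vertical planes per side;
6. union a tail box reaching 10 mm beyond the lower second molar;
7. subtract an ellipsoidal tongue body auto-placed 17.5 mm posterior to
   the lower-teeth centroid and sunk so the plate above it stays
   > 10 mm thick (verified by ray casting; a violation is an error);
8. combine the three parts (their interiors are disjoint by construction,
   so the union is exactly additive);
9. Taubin-smooth with every vertex within 0.5 mm of the dentition frozen,
   so the impression is bit-for-bit untouched.

Because real scans are patient data, the package ships a deterministic
synthetic anatomy generator (watertight height-field arches with
landmarked teeth; presets: normal occlusion, hypodontia, edentulous,
class III malocclusion) so the entire workflow is buildable and testable
without any patient geometry.

Under the hood is a compiled triangle-mesh engine written for this
package: BSP-tree constructive solid geometry with T-junction stitching
and a voxel-remeshing fallback, quickhull, watertight repair (hole
filling, orientation), binary/ASCII STL I/O, a parity-ray voxel volume
oracle, and feature-protected Taubin smoothing.

## Worked example

```r
library(stentforge)

anatomy <- generate_anatomy("normal", seed = 42)   # synthetic articulated scan
anatomy
#> <anatomy_model> preset 'normal', seed 42
#>   maxilla:  10496 faces | mandible: 10496 faces | 34 landmarks
#>   interincisal opening: 20.00 mm

design <- design_stent(anatomy, stent_config())
design
#> <stent_design> preset 'normal'
#>   final stent: 66.69 mL (396862 faces)
#>   min plate thickness: 11.62 mm (floor 10 mm)
#>   checkpoints: 9 in /tmp/...

summary(design)
#> Step-by-step volume trace:
#>  step              name volume_ml
#>     1             setup  27.91483
#>     2     outline_block  88.08248
#>     3          separate  88.08248
#>     4        trim_lower  27.55695
#>     5    upper_supports  34.32370
#>     6          add_tail  32.65712
#>     7 tongue_depression  32.05693
#>     8           combine  66.38063
#>     9            smooth  66.68739
```

Reading the trace: the outline block (step 2) is the expanded hull between
the two occlusal planes minus the dentition (~88 mL); step 3's checkpoint
is both halves together; steps 4–7 whittle the lower stent (the tongue
subtraction removes ~0.6 mL and leaves an 11.6 mm plate, above the 10 mm
floor); step 8's combined volume is exactly the sum of the three parts;
smoothing changes volume by well under 1 %. Each step also wrote a
watertight STL checkpoint for inspection in any mesh viewer.

The same run from a shell, via the bundled CLI:

```sh
Rscript inst/scripts/autostent generate --preset normal --seed 42 --out anat/
Rscript inst/scripts/autostent design --anatomy anat/ --out run/
Rscript inst/scripts/autostent measure --stent run/final.stl
```

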