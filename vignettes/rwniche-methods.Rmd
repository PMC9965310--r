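---
title: "Methods: semi-automated round window niche segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-automated round window niche segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwniche)
```

## The problem

Local drug delivery to the inner ear works by placing a drug-eluting
implant into the round window niche (RWN), the bony recess of the cochlear
promontory whose floor is the round window membrane (RWM).  A
patient-specific implant must fill the niche exactly: too large and it will
not pass the bony rim, too small and it will not sit pressure-tight against
the membrane.  The niche is small (a few millimetres), individually shaped,
and half-open toward the middle-ear cavity, which makes a manual slice-wise
segmentation of a cone-beam CT (CBCT) both slow and prone to
over-segmentation.  `rwniche` implements a semi-automated alternative: the
user supplies three anatomical landmarks and optionally refines a handful
of parameters; everything else — thresholds, membrane model placement,
niche filling, handle placement, surface export — is computed.

Two facts about temporal-bone CBCT drive the design.  First, in the 5 mm
working region around the niche essentially three intensity classes occur:
radio-dense bone (high), air in the middle-ear spaces (low), and the fluid
and soft tissue of the cochlea in between.  Second, the membrane itself is
invisible at clinical resolution, so the cochlea/middle-ear boundary must
come from a geometric model rather than from the image.

## The procedure

The pipeline (`run_semiauto_segmentation()`) executes these stages in
order; each stage logs its parameters and fitted values to a run report.

1. **Cochlear frame.**  From three fiducials (midmodiolar apex, midmodiolar
   basal turn, round-window centre) an orthonormal frame is fitted: z along
   the modiolar axis toward the helicotrema, x from the modiolar line to
   the round-window centre, origin at the RWM centre.  y completes a
   right-handed frame; a left/right working-orientation flag mirrors y so
   "toward the basal turn" keeps its meaning in either ear.

2. **Working region.**  A cubic region of interest (default edge 5 mm) is
   cropped around the round-window fiducial.  Retained voxels are exactly
   those whose centres lie in the closed cube; world coordinates are
   untouched.  If any voxel spacing exceeds the working resolution
   (default 0.1 mm) the region is upsampled by trilinear interpolation to
   an isotropic grid covering the same physical extent; finer volumes pass
   through unchanged.

3. **Membrane model.**  The RWM is modelled as a bilinear patch over four
   control points,
   $S(u,v) = (1-u)(1-v)\,p_{00} + u(1-v)\,p_{10} + (1-u)v\,p_{01} + uv\,p_{11}$,
   with an oval cut-out
   $((u-\tfrac12)/a)^2 + ((v-\tfrac12)/b)^2 \le 1$ marking the membrane
   proper.  Control points start from a mean model given as offsets from
   the RWM centre in cochlear-frame coordinates and can be replaced by
   user-fitted points.  A voxel is on the *cochlea* side if its nearest
   point on the (extended) surface falls inside the oval and its signed
   offset along the local normal — oriented toward the frame's +x, the
   middle-ear direction — is negative.  Everything else, including points
   projecting outside the oval, is *middle ear*.

4. **Bone threshold.**  A three-component Gaussian mixture (air,
   soft-tissue/fluid, bone) is fitted to the region's intensities by EM.
   The bone threshold is the intensity minimising the fitted mixture
   density between the soft-tissue and bone centres (the
   misclassification-minimising boundary under the model), with the
   centre midpoint as fallback if no interior minimum exists.  The
   comparison is inclusive (`>=`), conservative toward bone.  The user can
   override the threshold and optionally pre-smooth with a Gaussian of
   about one voxel for noisy scans.

5. **Niche fill.**  The niche is a "crater lake" whose bottom is the
   membrane.  Candidate voxels are non-bone, middle-ear-side, and within a
   *water level* `L` (Euclidean distance in mm) of a fill centre; the
   segmentation is the connected component (default 26-neighbourhood) of
   candidates containing the seed voxel nearest the membrane patch centre.
   The automatic level is the *spill level*: the largest `L` (binary
   search, quarter-voxel resolution) at which the fill does not touch any
   face of the working region — beyond it the lake spills over the lowest
   rim and escapes.  Every voxel records which rule excluded it
   (cochlea-side / bone / above level / disconnected), which later powers
   the rule-attribution analysis.

6. **Handle.**  A forceps handle — a cuboid whose distal quarter tapers to
   a vertical edge, arrow-like, marking orientation — is embedded one
   voxel into the middle-ear-facing surface of the body, long axis toward
   the basal turn by default.  Handle voxels overlapping bone are removed;
   the handle must stay 26-connected to the body, otherwise placement
   fails with advice to shrink it.

7. **Surface model.**  The body+handle mask is converted to a closed,
   2-manifold, outward-oriented triangle surface, optionally relaxed by
   shrink-free Taubin smoothing, and written as binary STL
   (84 + 50·n bytes).

Comparison utilities compute niche volume (voxel count x voxel volume,
body only), RWM contact area (kept voxels with a face neighbour on the
cochlea side, times the mean voxel face area), Dice and Jaccard overlap,
and the per-rule removal fractions obtained by applying the three niche
rules to an arbitrary (e.g. manual) segmentation.

## Parameters that matter

| parameter | unit | default | rationale |
|---|---|---|---|
| ROI edge | mm | 5 | covers the niche and its bony rim with margin |
| working resolution | mm | 0.1 | upsampling threshold; coarser inputs are interpolated so the implant surface is smooth |
| smoothing width | voxels | 0 | optional; ~1 voxel for noisy scans. The phantom has no partial-volume texture, so smoothing would only manufacture a boundary shell there (see below) |
| bone threshold | HV-like | auto | density minimum between the soft-tissue and bone peaks |
| oval semi-axes | – | (0.5, 0.5) | ellipse inscribed in the parameter square; only "oval" is anatomically given, the inscribed ellipse is the conservative choice |
| fill level | mm | auto (spill) | the largest level that does not escape the region |
| fill centre | mm | auto | centroid of candidate voxels within 1 mm of the membrane centre — a deterministic stand-in for the interactive drag handle |
| connectivity | – | 26 | least fragmentation on thin niches |
| handle w x l x h | mm | 1.0 x 1.5 x 1.0 | graspable with standard forceps at this scale |
| tip fraction | – | 0.25 | enough taper to read orientation, little volume loss |
| Taubin iterations | – | 10 | λ = 0.5, µ = −0.53: smooths voxel steps without shrinkage (implant fit is volume-sensitive) |

## Numerical choices

* **Crop rule.**  Voxels are kept when their centres lie in the *closed*
  cube; ties at the boundary are inclusive.  This makes crop sizes
  unambiguous and idempotent.
* **Trilinear interpolation** is evaluated in nested-lerp form,
  `a + t(b − a)`, which preserves constant fields exactly and never
  extrapolates (border clamping).
* **Patch projection.**  The nearest point on a bilinear patch has no
  closed form; we run a damped (Levenberg-style) Newton iteration in
  (u, v), vectorised over all query points, initialised from a 9 x 9 grid
  over the unit square, tolerance 1e-8 in (u, v), with a dense-grid
  fallback for non-converged points.  The surface is extended beyond the
  unit square for classification; how far the extension carries is a
  declared convention, not an anatomical statement.
* **Boundary ties.**  Points within 1e-9 mm of the surface are labelled
  middle-ear, so the implant never claims membrane voxels and rests *on*
  the membrane.
* **Histogram fit.**  EM on a subsample of at most 2e5 intensities.
  Components are initialised at the three most prominent local maxima of a
  smoothed 256-bin histogram (initial widths floored at one bin width);
  percentile-based initialisation was tried first and provably fails
  whenever one class (in practice bone) holds more than half the region,
  because all three percentiles then start inside the same peak.  The EM
  additionally carries a uniform background component (initial weight
  0.05, re-estimated) that absorbs partial-volume voxels belonging to no
  peak; without it, coarse-resolution inputs inflate the soft-tissue
  width several-fold and displace the threshold toward bone.  On clean
  tri-modal data the background weight converges to zero.  The reported
  model is exactly three Gaussian peaks.
* **Spill detection** equates "spilling over the crater rim" with the
  fill reaching a face of the 5 mm working region: the region is centred
  on the niche, so escape from the niche implies escape from the region.
  The level is Euclidean distance in world mm from the fill centre; no
  gravity axis is assumed.
* **Surface extraction** uses a binary surface net: one vertex per surface
  patch of each mixed 2x2x2 cell of voxel centres, placed at the cell
  centre, one quad per sign-changing lattice edge, quads oriented
  inside-to-outside.  Solid boxes mesh to their exact voxel bounding box
  (an isolated voxel of 0.1 mm spacing encloses exactly 0.001 mm³), which
  midpoint marching cubes or tetrahedra cannot do — they cut an isolated
  voxel down to an octahedron of about 17% of its volume.  Cells whose
  inside corners split into several face-connected components get one
  vertex per component, which keeps diagonal-contact configurations
  combinatorially 2-manifold.
* **Handle voxelisation** uses half-open intervals along every local axis,
  giving unbiased voxel counts on lattice-aligned bases.

## The synthetic phantom: what it emulates and what it does not

No clinical scans ship with the package, so validation runs against a
generated 5 mm bone phantom (`generate_phantom()`) with exact ground
truth.  It emulates: the tri-modal intensity statistics (air −1000, soft
tissue 0, cochlear fluid 50 — deliberately close to soft tissue so the
three-class model sees one middle peak — bone 1500, Gaussian noise
σ = 100); a niche cavity carved into bone behind a membrane surface
(planar, saddle, or hemispherical); a fluid duct (scala tympani surrogate)
behind the membrane, kept inside the membrane oval so the geometric
boundary is exercised; a soft-tissue slab and a middle-ear air slab at the
region borders, both disconnected from the niche, giving the histogram a
realistic class balance.

The `mouth` parameter models how the niche connects to the middle-ear
spaces outside the region, a point on which the desk-scale world is
genuinely underdetermined: `"drain"` (default) carves a narrow 0.16 mm
channel from the cavity to the +x face, giving the spill search an escape
path and the handle free air while keeping the over-fill small; `"sealed"`
encloses the cavity completely, the world in which exact fill recovery is
well defined; `"flush"` extends the pit walls to the region face, exposing
the spill-over mechanics directly.  Under the literal Euclidean-distance
water level, a flat-mouthed pit that is wider than deep can never be
filled exactly to its rim from an interior centre — over-mouth air is
always nearer the centre than the pit's own corners — so these three
variants, not one geometry, are what the fill semantics can be tested
against.

`degrade_to_clinical()` emulates the intraoperative scanner by
area-weighted box filtering to a coarser grid (exactly mean-preserving by
default) plus optional additive scanner noise; box averaging alone would
cut the native noise about five-fold and leave an unrealistically sharp
bone peak.

The phantom does **not** emulate: partial-volume texture at native
resolution (class values are pure per voxel — hence the pipeline's
smoothing default of 0 there), scanner physics (scatter, beam hardening,
rings), anatomical spirals (the cochlea is a straight duct), obstructed
niches (scar tissue, false membranes), or inter-patient shape variability.
A green end-to-end test therefore establishes that the geometry and
intensity machinery is self-consistent and recovers known truth under
realistic statistics — not clinical performance, which in the source
workflow rests on cadaver implantation tests.

At the 0.3 mm intraoperative resolution the phantom's drain channel is
below resolution, so coarse runs see a sealed niche; the resolution
acceptance run disables the handle stage for that reason (there is no free
air to host one) and scores segmentation recovery only.

## Known limitations

* The mean membrane model defaults are phantom-derived, not derived from
  micro-CT specimens; clinical use must supply site-specific offsets.
* The spill rule assumes the niche is interior to the working region;
  niches straddling the region boundary raise a geometry error rather
  than a partial result.
* Only rigid geometry is supported; no non-rigid fit of the membrane
  beyond moving its four control points.
* DICOM support targets uncompressed explicit-VR little-endian series
  (the common CBCT export); compressed transfer syntaxes are out of
  scope.
* The EM threshold is an initial estimate by design; heavily obstructed
  niches with tissue in the cavity will still require a user-refined
  threshold, as in the interactive original.
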