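---
title: "Parametric chiton girdle scales and flexible scaled armor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric chiton girdle scales and flexible scaled armor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chitonarmor)
```

Chitons are marine mollusks whose flexible girdle is covered by hundreds of
small, almost purely mineralized, overlapping scales. Each dorsal scale is a
diamond-based prism topped by a hook-like crown that imbricates over the
scale in front of it, so the array is simultaneously a continuous armor
(complete dorsal coverage) and a flexible sheet (rigid scales rotating on a
soft substrate, jamming into one another only past a bending threshold that
depends on direction). `chitonarmor` implements this system end to end: a
17-parameter generative solid model of one scale, mesh morphometrics that
recover the descriptor set used to characterise real scales, tessellation of
scale arrays into printable armor panels, and a rigid-scale kinematic
bending model that finds inter-scale contacts and the curvature at which
interlocking begins.

## The parametric scale model

A scale is scaffolded by three principal sections, carrying 20 geometric
markers controlled by 17 free parameters:

* **BASE** (4 parameters): a diamond in the base plane with `width` (W),
  `length` (L) and two corner fillet radii. The fillets are circular arcs;
  the pre-fillet diamond is enlarged so the filleted contour still attains
  the nominal W and L extents. The base is prismatic: its cross-section
  does not change along its height.
* **YZ profile** (10 parameters): seven markers in the sagittal plane —
  the two base corners (inherited from L), the posterior and anterior
  inflection points (`h1`, `setback_post`; `h1_ant`, `setback_ant`), the
  dorsal apex (`apex_y`, `height`), the hook tip (`tip_y`, `tip_z`) and an
  underside marker (`under_y`, `under_z`). The basal profile edges are
  straight lines (the prism); the hook is a clamped cubic spline that
  leaves the posterior inflection tangentially, crests horizontally at the
  apex (so `height` is the exact height maximum), and meets the anterior
  inflection in a corner — the notch where the hook springs from the base
  and where the imbrication angle is defined.
* **XZ crown** (3 parameters): the lateral half-width law along the scale,
  as fractions of W/2 at a mid station and near the tip.

Because several parameters place more than one marker (for instance `h1`
positions both basal-edge top corners) and the sections inherit W, L and H
from one another, 17 parameters suffice for 20 markers.

```{r}
p <- scale_params()          # the Rhyssoplax canariensis shape
print(p)
```

### Angle conventions

The two angles that characterise imbrication are defined on the transverse
projection (the silhouette seen along the width axis), with one shared
convention between the generator and the measurement code:

* **Inclination β**: the tilt of the posterior basal edge away from the
  base-plane normal. An upright prism has β = 0; a strongly reclined base
  (as in *Ischnochiton australis*) approaches 60°. This follows the
  published usage in which a larger β means a greater inclination.
* **Imbrication α**: the interior angle at the inflection point between the
  basal edge and the hook axis, where the hook axis is the line fitted to
  the *underside of the hook overhang* — the surface that rides over the
  neighbouring scale. Writing δ for the elevation of that line,
  α = 180° − β − δ. A straight extrusion (no hook) degenerates to α = 180°,
  and the overlap-capability condition α + β < 180° is equivalent to δ > 0:
  the hook underside must climb, so that it can shingle over the next
  scale's crown. Scales with small α (≈90°, *I. australis*,
  *Lepidozona mertensii*) have steeply climbing, tightly curled hooks;
  large α (≈130°, *I. lentiginosus*) means an open, barely curled hook.

### Lofting

The solid is built by sweeping closed cross-sections along the medial spine
of the YZ profile. The two branches of the profile (posterior: base →
apex → tip; anterior: base → notch → tip) are paired point-by-point — at
equal height inside the prismatic base, so basal sections are exact
horizontal diamonds, and by proportional arc length in the hook — and each
pair's chord spans one section. Sections are closed periodic-spline ovals
through the four extreme points (the two chord ends and the two lateral
extremes from the width law), morphing from the filleted diamond over a
short blend above the inflection. Two crown-section styles exist as a
construction option: the default `crescent` (a transversely arched shell,
full thickness at the midline, thinning and drooping toward the flanks, as
in the natural cup-like crown) and `slab` (near-rectangular sections with
flat lateral flanks, the simplified printable crown used by the armor
prototype). The mesh is capped at the base and tip and is watertight by
construction.

A note on section planes: planes exactly normal to the spine fail for
strongly inclined scales (near the base they exit through the base plane
before reaching the anterior profile branch), so the sections are framed by
the branch-pair chords instead. For slender shapes the chords are nearly
spine-normal; the residual obliquity is recorded in the
`section_obliquity` attribute of the mesh.

Default resolutions are 64 sections × 64 profile points; volume and the
area descriptors change by less than 0.5% when both are doubled, which the
test suite verifies. All operations are deterministic.

```{r, fig.width = 7, fig.height = 3.5}
m <- loft_scale(p, 48, 48)
plot(m)
```

## Morphometrics

`measure_scale()` recovers the descriptor set from any watertight scale
mesh (generated or loaded from STL/OBJ/PLY and re-posed with
`canonical_pose()`):

* W and L from the base footprint (the cross-section just above the base
  plane — using the full bottom silhouette would let the hook overhang
  inflate L);
* H from the mesh extent; h1 from the point where the posterior silhouette
  edge departs from the fitted basal line, using a two-threshold crossing
  with quadratic-bias removal (the departure from a straight line grows
  quadratically past the true corner, so the crossing points at two
  thresholds extrapolate back to the corner);
* β from the basal-line fit, α from the underside-line fit described
  above (the fit spans the rising flank from the notch, skipping a short
  lead-in past the footprint edge and the crest rounding);
* A1 (the overlapped area) as the transverse silhouette area forward of
  the vertical through the footprint's front edge, A2 as the remainder;
  silhouettes are computed by scanline union of triangle shadows;
* V and the volume centroid by the divergence theorem.

The identities H = h1 + h2 and A_total = A1 + A2 hold exactly by
construction. A straight prism yields a flagged degenerate record
(h1 = H, α = 180°); a doubly-curved profile (two inflection points, as in
*L. mertensii*) raises the `multi_inflection` flag, detected as
opposite-signed bending runs of the posterior silhouette edge that each
accumulate at least 12° of turning.

```{r}
rec <- measure_scale(m)
print(rec)
```

The basal centre-of-mass property — the claim that a scale intrinsically
resists tilting under a normal compressive load — is implemented as a
support test: the vertical line through the volume centroid must pass
through the base footprint. (An earlier formulation, centroid height below
h1, would couple the check to the crown's height rather than to tilting
mechanics: a tall but balanced scale does not tip, while a low centroid
hanging beyond the footprint does.)

```{r}
basal_com_check(rec)
```

## Species presets

Ten bundled presets cover the two chiton families studied
(five Chitonidae, five Ischnochitonidae). The published record gives
per-species descriptor targets only as ranges and extremes (α from about
90° to about 130°, β from about 10° to about 60°, h1/H near 0.5 for
*Chiton cumingsii* and *Ischnochiton contractus*, volumes from 0.005 mm³
to 0.1 mm³, a doubly-curved profile for *L. mertensii*), so the presets
are calibrated — their marker values are the package's own, adjusted until
the *measured* morphometrics of the generated meshes fall inside the
recorded ranges stored with each preset. `preset_check()` re-runs those
checks, and in every species the measured α + β stays below 180°
(overlap capability) and the centre of mass is basal.

```{r}
species_presets()
rec_a <- measure_scale(loft_scale(preset_params("Ischnochiton australis"), 32, 32))
c(alpha = rec_a$alpha, beta = rec_a$beta)
```

## Armor assembly

`tile_uniform()` arranges identical scales on a diamond lattice generated
by two families of intersecting parallel lines, with the cell aspect
matched to the base's W/L and the lattice constant inflated so the nearest
base-to-base surface gap equals the prescribed spacing d (the printed
prototype uses L = 10 mm, d = 0.5 mm, d/L = 5%). `build_substrate()`
constructs the embedding slab — thickness equal to the scale's inflection
height h1 (4.1 mm for the prototype) — cell by cell as the prism between
the lattice cell and the sheared base contour, which is exact for
prismatic bases and avoids mesh booleans; the sockets are therefore the
swept base footprints, and the authoritative substrate volume is computed
by cross-section integration of the actual scale solid. `tile_gradient_fan()`
places scales at the intersections of two expanding line pencils with size
factors proportional to the square root of the local cell area,
reproducing the proximal-to-distal size gradient of the natural girdle;
with zero angular divergence it degenerates to the uniform lattice.
`tile_on_surface()` maps the lattice onto parametric hosts (plane,
cylinder, sphere cap) with each scale's frame aligned to the surface
normal and its size clamped by the inverse of the local maximum curvature;
arbitrary mesh hosts are out of scope. Panels export as binary STL, one
file per print material (rigid scales, flexible substrate).

### The prototype scale

The printed prototype's dimensions (L = 10 mm with embedded height
h1 = 4.1 mm) imply h1/L = 0.41, which no scale obeying the measured
mid-girdle ratios (h1/H 0.3–0.4 with H/L 0.5–0.6, hence h1/L ≈ 0.2) can
reach. The armor prototype therefore carries its own shape
(`prototype_params()`): a taller scale with a broad slab crown whose
flanks face the diagonal neighbours across narrow slots (about 0.07 mm at
rest at the working mesh resolution of 28 × 28), while the hook rides with
roughly 0.5 mm of daylight over the scale in front. The assembly functions
default to this shape.

## Bending and interlocking

`bend()` wraps the substrate midsurface isometrically onto a cylinder of
prescribed signed curvature κ whose axis lies at angle φ to the scale
width axis (φ = 0: the panel curls along the hook direction, the bend
toward the animal's body; φ = 90: it curls along the width), and carries
each rigid scale with its base site. This uniform-curvature kinematic
surrogate replaces the experiment's pinned post-buckling deflection: the
experiment's curvature is concentrated at mid-span, and a single κ is the
clean control variable at desk scale; forces, friction and post-contact
sliding are out of scope, so the model claims contact topology and onset
only. Scales are rigid and the midsurface inextensible, justified by the
thousandfold modulus contrast between the printed scale and substrate
materials.

`detect_contacts()` reports every scale pair closer than a tolerance
(default 5% of the spacing d) with witness points and the lattice
neighbour class; `onset_curvature()` bisects for the smallest concave κ at
which any interior scale makes contact (to 10⁻⁴ mm⁻¹). On the 7 × 7
prototype panel the model reproduces the interlocking topology of the
experiment: past onset at φ = 90° every interior scale carries exactly
four contacts, all with its diagonal neighbours, and at φ = 0° the first
contact is the hook meeting the back of the scale directly in front
(`hook_row`). Convex bending (scales facing outward) stays contact-free
far beyond the concave onset curvature; only at several times that
curvature would the embedded bases — in reality separated by substrate
material — approach one another.

One property of the experiment is **not** reproduced by this surrogate and
the corresponding check is expected to fail: the published orientation
ordering has stiffening onset earliest at φ = 90° and latest at φ = 0°,
whereas first-contact kinematics on the rigid model gives
κ*(60°) ≤ κ*(0°) < κ*(90°). The reason is structural rather than a matter
of calibration. Whenever the 60° and 90° orientations engage the same
diagonal interface, the 60° closure rate is the aligned sum of a pitch and
a roll component and therefore always exceeds the pure-roll rate at 90°;
and any interface whose gap normal has a vertical component closes faster
under pitch (lever arm: the row pitch) than under roll (lever arm: the
column offset), which favours contact at small φ. The experimental
ordering instead reflects what happens after contact — at 90° the scales
contact early but slide with little resistance, and the substrate shears —
which lies outside a rigid-scales-on-an-inextensible-midsurface model.
The package reports the onset curvatures as computed and leaves the
ordering test red rather than bending the model to match.

```{r, eval = FALSE}
asm <- tile_uniform(assembly_spec(rows = 7, cols = 7, resolution = c(28, 28)))
onset_curvature(asm, phi = 90)
```

## Numerical choices and limitations

* Units are millimetres throughout; no unit inference.
* Scanline counts: 600 silhouette scanlines per projection in
  `measure_scale()` (descriptor changes are below 0.5% against doubled
  resolution and within 1% of brute-force voxel and raster oracles, which
  the tests verify against independent ray-parity and pixel-counting
  implementations).
* Contact queries use exact point-to-triangle distances two ways with
  bounding-box pruning; accuracy is bounded by the facet sagitta, so
  contact work uses meshes of at least 28 × 28 and quotes rest clearances
  at that resolution.
* Mesh resolutions in the test-suite and acceptance runs (24–64 sections)
  are chosen so the full suite completes on a single CPU in minutes; the
  convergence tests justify them.
* The synthetic fixtures (boxes, sheared prisms, a hooked prism, an
  overhanging mushroom, jittered presets) emulate the geometric features
  the estimators rely on — straight basal edges, a single inflection, an
  overhanging hook — but not imaging artefacts of real micro-CT meshes
  (holes, noise, partial scans); `read_mesh()` performs only basic
  validation, so passing tests say nothing about robustness to damaged
  scans.
* Surface micro-ornamentation (dorsal ridges at tens of micrometres,
  posterior conical bumps) and the basal dimple and pores of real scales
  are omitted, as in the printed prototypes; they do not enter the
  descriptor set.
* The d/L = 5% spacing, the 4.1 mm substrate thickness, and the printed
  panel's scale length are taken directly from the prototype's published
  dimensions; grid counts default to 7 × 7 for bending work, a reduced
  panel that keeps the kinematic analyses fast while retaining a full
  interior neighbourhood.
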