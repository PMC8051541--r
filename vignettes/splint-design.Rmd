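---
title: "Designing lattice splints from limb scans: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing lattice splints from limb scans: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A printable lattice splint is a clamshell of triangulated bars that hugs a
limb segment at a constant clearance. Designing one from a surface scan
traditionally takes three interactive tools: one to offset and crop the
scan, one to relax the bar lattice, and one to turn the wireframe into a
solid with fastening blocks and a two-piece split. splintfab scripts that
whole chain behind a single configuration, so a run is reproducible from a
config file and a seed.

The geometric logic that ties the pipeline together: the printed bars have
radius *r* (2 mm by default), so their centerlines must lie on a surface
offset *r* above the skin. The offset distance and the strut diameter are
therefore a single degree of freedom, and `pipeline_config()` refuses
configurations that break the tie unless explicitly overridden.

## Pipeline stages and their models

### Synthetic limb (`generate_limb()`)

No scan data ships with the package; a parametric generator stands in for
the scanner. It lofts superellipse cross-sections
(`|x/a|^p + |y/b|^p = 1`) along a gently bowed axis with linearly tapered
semi-axes, adds a Gaussian radial bump on one side (a stand-in for a bony
prominence such as the ulnar styloid), and perturbs the radius with seeded
noise that is smoothed with a fixed-width moving average so the normal
field stays well defined — raw white noise would break the per-vertex
normal offset. The default wrist preset is 250 mm long with proximal
semi-axes (45, 35) mm, distal (30, 25) mm, a 4 mm bump, 0.3 mm noise, and
about 15k triangles, which is the scale a structured-light scan of a
forearm delivers after decimation.

What the generator does *not* emulate: holes, flipped normals, scanning
spikes, self-contact between limb and hand, or anatomical detail (fingers,
tendons). Tests passing on synthetic limbs therefore demonstrate the
pipeline's geometric correctness, not robustness to pathological scans;
real scans should be repaired before input (the package validates but does
not repair).

### Offset, crop (`offset_surface()`, `plane_cut()`)

The offset moves every vertex by *d* along its angle-weighted unit normal.
This is exact for spheres and cylinders and accurate wherever the surface
curvature radius is large against *d* — true for limbs at *d* = 2 mm. It
preserves connectivity exactly and cannot create new topology, which is
why it is preferred over a signed-distance offset here; the price is that
concave creases tighter than *d* would self-intersect. The package detects
(vertices landing closer than 0.95 *d* to the input) and warns, but does
not repair; repairs are out of scope.

Cropping clips triangles exactly against configured planes, caching the
edge–plane intersection per mesh edge so adjacent triangles share the new
rim vertices and the cut boundary is a clean polyline on the plane. No cap
is added: the shell is meant to stay open.

### Isotropic remeshing (`remesh_isotropic()`)

Interactive drafting tools expose remeshing as a single button; here the
equivalent is the standard incremental scheme: per sweep,
split edges longer than 4/3 *h*, collapse edges shorter than 4/5 *h*
(guarded by the link condition and an upper length bound), flip edges
toward valence 6 (4 on the boundary), smooth tangentially, and project
every vertex back to the input shell. Boundary vertices are constrained to
the input's boundary polylines so the cropped profile survives, and
boundary vertices where the rim turns by more than 30° are pinned
outright — without that, smoothing would shave corners off straight-sided
profiles. Flips are skipped when both endpoints are boundary vertices;
valence targets are ill-defined on a rim. An already uniform equilateral
grid is an exact fixed point of the sweep, which is the property that
makes the target edge length *h* meaningful.

The demo preset uses *h* = 12 mm, chosen so the relaxed lattice produces
bar spacings typical of printed wrist splints; there is no canonical
density, so this is a package default.

### Mass-spring relaxation (`optimize_lattice()`)

The lattice edges become Hooke springs with one shared rest length
`L0 = fscale * sqrt(sum(L^2) / E)` (the uniform-density scaling of the
mass-spring mesh generator this stage follows). Bilateral springs are the
default — compressed springs push their endpoints apart *and* stretched
springs pull them together, which is what equalizes triangle sizes in both
directions; `repulsive_only` reproduces the strictly repulsive variant.
Integration is semi-implicit Euler with a multiplicative viscous factor:

```
v <- (v + dt/m * F) * (1 - c*dt/m),   x <- x + dt * v
```

with defaults k = 1, m = 1, dt = 0.2, c = 1 (damping factor 0.8),
tolerance 1e-3·L0 on the per-step displacement, and a 1000-iteration cap.
The damping factor must lie in (0, 1): the velocity of a force-free node
then decays monotonically, which is what stabilizes an otherwise
oscillating spring system. These constants are package choices, stable on
all presets.

Two choices deserve their rationale spelled out:

* **`fscale = 1.0`, not the classical 1.2.** The 1.2 constant comes from
  planar mesh generation, where excess rest length pressurizes the network
  and the pressure escapes through the domain boundary while
  retriangulation repairs the connectivity. Neither mechanism exists here:
  the lattice keeps its topology (no flips or collapses during
  optimization, by design), its nodes are projected onto a shell of fixed
  area, and its rim is inextensible. Under those constraints L0 above the
  RMS edge length over-pressurizes the network and compressed spring
  chains buckle into sliver triangles — the opposite of the equalization
  the stage exists for. With `fscale = 1.0` the rest length equals the RMS
  edge length, the net pressure vanishes, and relaxation cleanly shrinks
  large triangles and opens small ones.
* **Projection every step.** A pure mass-spring relaxation would drift
  off the curved shell; the package re-projects every step (closest point
  on the shell for interior nodes, closest point on the rim polyline for
  boundary nodes, with the off-surface velocity component removed)
  because the printed splint must keep the constant 2 mm clearance that
  motivated the offset in the first place.

The graded-density preset used to demonstrate and regression-test the
equalization warps the draft lattice axially with
`t -> t - a*sin(2*pi*t)/(2*pi)` (a = 0.6, a 4:1 density ratio). The warp's
derivative stays in [1−a, 1+a], so it grades density without folding
triangles — an earlier power-law variant created degenerate slivers at
the rim, which says nothing about drafting-tool output and everything
about a bad warp.

### Solidification (`strut_solid()`, `attach_blocks()`, `split_solid()`)

The printable solid is the union of a 4 mm sphere at every node and a
4 mm cylinder along every edge; the package draws each edge as a capsule
(cylinder plus hemispherical caps), which is the same union with smooth
junctions by construction. The union is evaluated as a signed distance
field on a voxel grid (default pitch = diameter/8 = 0.5 mm) and extracted
with marching tetrahedra on a 6-tet cube decomposition, welding extraction
vertices by grid-edge key so the result is watertight by construction.
Robust exact booleans over hundreds of mutually tangent primitives are the
known failure mode of mesh CSG, which is why the voxel route is the
default and the only implemented method; the error it introduces is
bounded by the pitch.

Two refinements keep that error small:

* extracted vertices are Newton-projected onto the exact primitive SDF
  zero-set (3 iterations, gradient by central differences, step clamped to
  2 mm), which removes the inscription bias of linear interpolation —
  volumes of spheres and capsules then land within ~1% of the closed
  forms at the default pitch;
* triangles whose area collapses under that projection (three vertices
  landing colinear) are removed by collapsing their shortest edge, a
  closure-preserving operation, iterated until no degenerate face remains.

Fastening blocks are 20 x 12 x 8 mm boxes with a 4 mm through-hole,
anchored on the shell's lateral extremes at three axial stations on each
side (six in total), hole axis along the split-plane normal — the
clamshell bolt layout. There is no canonical block size; these are
package defaults. Holes are drilled by subtracting
the hole cylinder in the same SDF evaluation, and a probe-segment test
verifies each channel is open (a probe along the hole axis crosses no
surface).

The two-piece split intersects the same SDF with each half-space of the
split plane on the same grid, so the two capped pieces share their cap
exactly and their volumes sum to the whole. For solids without primitive
provenance (e.g. meshes read back from STL) the field is built from the
mesh itself: closest-point distance signed by z-column ray parity, exact
in a narrow band around the surface and chamfer-approximated elsewhere
(only the sign matters away from the interface), with extraction vertices
snapped back to the source mesh or the plane, whichever generated them.

## Numerical choices

* Weld tolerance on read: 1e-5 mm. STL stores facets independently but
  duplicated corners are written from the same number, so any tolerance
  above float32 noise welds them; solids refined onto creases can carry
  genuine ~2e-5 mm vertex pairs that a looser weld would pinch together.
  Solid cleanup collapses edges under 1e-3 mm (link-condition-guarded) so
  no connected feature sits near the weld scale.
* Degenerate-face area threshold in validation: 1e-12 mm².
* Self-intersection checking is a grid-pruned sample capped at 2e5
  triangle pairs by default (`max_pairs = Inf` runs the full pruned
  check); coplanar pairs are not tested, which is fine for its role as a
  diagnostic on offset shells.
* Ray-cast volume oracles jitter the ray grid by irrational fractions of
  the pitch so rays never hit vertices or edges of axis-aligned fixtures;
  columns with odd crossing parity are discarded.
* Marching-tetrahedra nudges exact zero field values to +1e-12 so no
  extraction vertex coincides with a grid vertex.
* Units are millimetres everywhere; there is no unit conversion anywhere
  in the package.

## Problem sizes

The demonstration pipeline runs the wrist preset at ~15k input triangles,
a ~9k-triangle cropped shell, a ~270-node draft lattice, and an SDF grid
of roughly 11M voxels at 0.5 mm pitch; end to end this takes about a
minute on one core, dominated by the three SDF evaluations (solidify,
blocks, split). The test suite reuses one cached demonstration run for
everything that needs the final solid.

## Known limitations

* Offset self-intersection is warned about, never repaired; limbs with
  creases tighter than the offset distance need a smaller offset or a
  repaired scan.
* The optimizer never changes connectivity, so a draft lattice with a
  grossly wrong density cannot be fixed by relaxation alone — re-draft
  with a different target edge length instead.
* The voxel union's geometric error is pitch-limited; printed tolerances
  below ~pitch/2 require a finer `voxel_pitch_mm` and proportionally more
  time and memory.
* `exact_boolean` is reserved in the interface but intentionally not
  implemented.
* OBJ support is the minimal `v`/`f` dialect; PLY/3MF/AMF, colors and
  textures are out of scope.
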