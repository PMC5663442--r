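---
title: "Mapping catchment volumes of panoramic snapshots: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping catchment volumes of panoramic snapshots: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`catchvol` quantifies, in three dimensions, the navigational information a
panoramic snapshot carries: within what volume around a goal does a
descent of panoramic image differences converge back onto the goal? This
vignette explains the models behind each stage, the parameters that
matter, what the synthetic worlds do and do not emulate, and the numerical
choices the implementation makes.

## The snapshot model

A homing agent stores a greyscale panorama at the goal and compares it to
current views by the root-mean-square pixel difference on the 0–255 grey
scale. Two difference functions carry the information:

* the **rotIDF**, obtained by rotating the reference about the vertical
  (yaw) axis against a view — rotation moves *all* image regions, so its
  minimum is a robust compass cue;
* the **transIDF**, obtained by comparing same-orientation views at
  displaced positions — translation moves image regions in proportion to
  the inverse distance of the features behind them, so its gradient
  encodes position, rising steeply near close features and gently in open
  terrain.

The model assumes a static world with constant illumination, panoramic
(full-sphere) vision at low resolution, and an agent that can hold a
compass orientation while translating, so the transIDF is evaluated at a
fixed orientation. These match the regime the simulation targets; moving
shadows, wind and sensory noise are outside it.

## Rendering: cube-map to equirectangular

Views are rendered by six 95°×95° pinhole cameras (north, east, south,
west, up, down; 128×128 pixels each at full scale) and spherically
reprojected to a 384×192 equirectangular raster — 360/384 = 0.9375° per
pixel. A nominal "0.9°" per pixel is the rounded form of the same number;
the code uses the exact value. Conventions, fixed once and used
everywhere:

* world axes x = east, y = north, z = up; azimuth 0° = north, increasing
  clockwise through east; column `c` has centre azimuth `(c − 0.5)·360/384`;
* row `r` has centre elevation `90 − (r − 0.5)·180/192`, so the horizon
  lies exactly on the boundary between the two middle rows and the
  above/below-horizon halves have equal pixel counts — which is also why
  full-sphere rms² is exactly the mean of the two hemisphere rms² terms;
* pixel centres sit at half-integer offsets; no row touches the poles, so
  no singular view directions arise;
* projection picks, per output pixel, the cube face whose axis dominates
  the view direction and samples it bilinearly. The 5° of field beyond 90°
  is purely overlap margin: it guarantees the bilinear neighbourhood stays
  interior to the face. A nearest-neighbour mode exists for bit-exactness
  experiments;
* greyscale flattening uses the ITU-R BT.601 luma weights
  (0.299 R + 0.587 G + 0.114 B), the weights behind the standard
  BGR-to-grey conversion, rounded and clipped to [0, 255]; converting
  twice is idempotent.

The r.m.s. runs over the raw raster without solid-angle weighting: polar
rows count as much as equatorial ones. That matches the plain-pixel
definition of the difference functions; a weighted variant would change
absolute values but not the structure of the analysis, and is deliberately
not the default.

## The synthetic worlds

No deposited 3D reconstructions of real sites exist to ship, so the
package generates outdoor-like worlds procedurally; the generator is a
first-class, tested module, not a fixture. A scene is a textured ground
plane, trees (cylinder trunks carrying sphere canopies), optional small
ground clutter, a sun, a uniform sky, and an optional distant background
sphere. Shading is ambient-only: a surface shows its albedo, darkened by a
constant factor where the line to the sun is blocked (binary hard
shadows). This is the simplest model that still produces the two features
that dominate near-ground image differences: fine-scale ground contrast
and sharp shadow edges.

Parameters that matter, with defaults:

| parameter | default | meaning |
|---|---|---|
| `ground_texture$noise_scale` | 0.5 m | correlation length of the ground albedo pattern (band-limited, multi-octave value noise; C1-smooth so nearby views differ smoothly) |
| `albedo_lo`, `albedo_hi` | 0.25–0.75 | ground reflectance range; their spread sets ground contrast |
| `sun$elevation_deg` | 45° | with azimuth, fixes shadow geometry |
| `sun$shadow_darkening` | 0.5 | multiplier on shadowed albedo; 1 disables shadows entirely |
| `background$sphere_radius_m` | 500 | radius of the distant panorama sphere |

The background sphere default follows the "1 km diameter" reading of the
source material; the alternative "at a distance of 1 km" reading would
double it, and the radius is configurable precisely because the two
readings disagree. At grid scales of meters the difference is sub-pixel
parallax either way.

Three presets fix the scene classes used in examples and tests:
`site1_like` (near trees, clutter within 3 m, strong shadows, fine ground
texture — a cluttered nesting site), `site3_like` (a few large trees at
15–30 m, weak coarse texture — an open woodland park) and
`four_landmarks` (four identical trees 90° apart over featureless ground,
shadows off — an exactly four-fold symmetric aliasing test-bed, whose
self-rotIDF has four indistinguishable minima). Tree and clutter placement
derives from the seed by coordinate hashing, so a preset plus a seed is a
complete world description; the same specs ship as YAML under
`inst/extdata/`.

What the generator does **not** emulate: photogrammetric reconstruction
artefacts, meshes and photographic textures, spatially varying
illumination, vegetation motion, and the specific geometry of any real
site. Passing tests therefore demonstrate properties of the *method*
(projection geometry, IDF structure, climb classification, ablation
machinery) and qualitative scene-class effects, not quantitative
predictions for any real habitat: absolute IDF values and catchment sizes
from real reconstructions depend on scene content this generator does not
reproduce.

## Grids and the transIDF

Sampling grids are axis-aligned regular lattices; a cube of side `s` at
spacing `d` has `round(s/d) + 1` samples per axis inclusive of both
boundary planes — 51 for 5 m at 10 cm and for 10 m at 20 cm. The grid is
rendered once into a panorama stack and reused across reference heights
and mask modes; only a change of background re-renders, because the
background changes what missed rays see, whereas horizon masking is a
pixel-domain operation on existing renders. Stacks live in memory and
volumes serialize to plain text (long-format CSV plus a JSON sidecar);
panoramas write as 8-bit PNG with a CSV manifest.

The transIDF value at the reference voxel is pinned to exactly 0 (it is a
self-comparison; floating-point assembly cannot perturb it), and all
values lie in [0, 255].

## Catchment extraction

From every grid point a hill climb repeatedly moves to the steepest
descending 26-neighbour, where the descending gradient toward neighbour
`n` is `(V1 − Vn)/distance` with `distance` the Euclidean separation
(`d·√k` for a k-axis diagonal at spacing `d`). A step is taken only if the
gradient **strictly exceeds** the threshold — 10% of the maximum of the
reference's self-rotIDF, per meter — so the threshold models the agent's
sensitivity to image differences relative to the image structure at the
goal. Terminal classes:

* `success` — the climb reached the reference voxel;
* `false_minimum` — no neighbour descends at all;
* `subthreshold` — neighbours descend, but none steeply enough;
* `left_volume` — the climb sits on the grid boundary and the only
  supra-threshold descent points outward, judged by one-sided
  extrapolation through the opposite in-grid neighbour. On a bounded grid
  a climb cannot literally exit, so this class is necessarily an
  interpretation: it marks basins that continue beyond the sampled cube.

Ties between equally steep neighbours break by a fixed lexicographic
order (dz, then dy, then dx ascending); on textured scenes exact ties have
measure zero, so the choice only pins down determinism. Because every step
strictly decreases the IDF, paths cannot revisit a voxel and termination
is guaranteed. Full-volume extraction memoizes: a climb that steps onto an
already-classified voxel inherits that status. Climbs are deterministic,
so this is exactly equivalent to running every climb to its end — an
equivalence the test suite asserts rather than assumes.

Raising the threshold can only remove steps, so catchments shrink
monotonically with threshold; this invariant is tested on random volumes.
A threshold of 0 (e.g. from a constant reference image, which has a zero
self-rotIDF) degenerates to unthresholded climbing and is flagged with a
warning rather than an error.

### The continuous cross-check

An independent gradient-descent walker validates that discrete climbing
tracks a genuine continuous gradient: trilinear interpolation of the
volume, central finite-difference gradients (half-spacing offsets, clamped
to the hull), a fixed step of a quarter grid spacing, no threshold.
Success means coming within one grid spacing of the reference location —
the stop radius is configurable because the success criterion for a
continuous walker on a discrete volume is inherently a convention; one
spacing makes the continuous and discrete success conditions commensurate.
The walker fails by leaving the hull, by gradient collapse away from the
goal, or by exhausting its step budget. The acceptance suite measures the
overlap of the two success sets on the open preset world and requires at
least 90% of their union.

## Problem sizes and determinism

Full-scale runs (51³ grids at 384-pixel panoramas) are supported but are
hours-scale; the package's own tests and the reproduction script use a
desk-scale standard condition chosen once: the `site3_like` preset
(seed 1), an 11³ grid at 0.2 m spacing centred 1.2 m above ground (so the
0.2 m and 2.0 m reference heights lie on grid planes), 96-pixel-wide
panoramas with 32-pixel cube faces. On these conditions the shipped-seed
expectations are that the catchment of a 2 m reference is at least as
large as that of a 0.2 m reference, and that restricting comparison to
above-horizon pixels does not enlarge the ground-reference catchment.
Both are *tendencies* of open scene classes, asserted on the shipped
preset seed; across arbitrary regenerated worlds individual layouts can
reverse the height effect (a tree standing close to the grid can make the
ground reference unusually informative), which is why the property is tied
to the shipped conditions rather than claimed universally.

Everything is deterministic given the inputs: scene content derives from
the seed via coordinate hashing (no global RNG state is consumed), ray
tracing is a pure function of scene, origin and direction, and repeated
runs of the same configuration produce byte-identical manifests and CSVs.
Ray–primitive intersections use a 1e-9 m tolerance; nearest-hit ties break
by primitive declaration order (ground, then each tree's trunk and canopy
in list order, then clutter).

## Known limitations

* Ambient-plus-hard-shadow shading has no sky gradient, no soft shadows
  and no specularities; shadow edges are one pixel sharp at any
  resolution.
* The ground plane is finite; near the horizon, rays can pass beyond its
  edge to the sky, so horizon-adjacent pixels blend ground and sky.
* rotIDFs are computed at one-column (0.9375°) granularity; sub-pixel
  rotation is out of scope.
* No image preprocessing (contrast normalisation, difference-of-Gaussians
  filtering, skyline binarisation) is applied; the comparison is raw
  pixels, and masking is the only view manipulation.
* The `left_volume` class depends on a one-sided boundary extrapolation;
  basins that end exactly at the boundary with a flat outward gradient are
  classified `subthreshold`/`false_minimum` instead.
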