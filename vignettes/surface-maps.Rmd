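---
title: "Building seamless surface maps of rotating fruit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building seamless surface maps of rotating fruit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheromap)
```

## The problem

Roller conveyors in fruit-inspection machines spin each piece of produce
about a roughly vertical axis while a fixed overhead camera captures a dozen
or so frames, together covering about a full turn. Grading from those frames
individually is wasteful and error prone: consecutive views overlap heavily,
small defects get counted several times, large defects are never seen whole,
and global quantities such as the fraction of green (unripe) surface are hard
to define across overlapping views. spheromap fuses the view sequence into a
single longitude x latitude surface map on which each surface point appears
exactly once (or, when the fruit turns more than 360 degrees, at a known
360-degree offset), so every analysis can run once per fruit.

Because rollers slip, the rotation per frame is not known from the machine;
it must be estimated from the images themselves. That estimation — and
everything downstream — rests on a simple geometric model.

## Geometric model

The fruit is a **spheroid**: an ellipsoid with principal radii
$(r_x, r_y, r_z)$, $r_x = r_z$, so the distinct axis (oblate: shorter,
prolate: longer, spherical: none) is the fruit $y$-axis. The camera is
orthographic at the scale of interest: each view has coordinates $x$
rightward, $y$ upward, $z$ toward the camera, with origin at the fruit's
silhouette centroid. A *fruit frame* is the rotation matrix whose columns
$(\mathbf v_x, \mathbf v_y, \mathbf v_z)$ are the fruit axes expressed in
view coordinates.

A map cell at longitude $\phi$ and latitude $\lambda$ corresponds to the
surface point

$$X = r_x\cos\lambda\cos\phi,\quad Y = r_y\sin\lambda,\quad
  Z = r_z\cos\lambda\sin\phi,$$

and its position in view $i$ is $x_i\,=\,(X,Y,Z)\cdot$ the axis columns of
frame $i$; the point is visible there when its $z_i > 0$. Conversely, a view
pixel is lifted to 3D by intersecting its viewing ray with the spheroid
(`surface_height()`), projected on the fruit axes, and inverted to
$(\phi, \lambda)$. Although the fused image is often described as
"Mercator-like", a uniform angular step in both $\phi$ and $\lambda$ is an
equirectangular (plate carrée) grid — linear in latitude, which is what this
package implements.

With the axis convention above, the centre of a view always shows longitude
$90^\circ$ plus the cumulative rotation, because the visible apex has
$(X,Y,Z) = (0,0,r_z)$.

## Pipeline and the choices behind it

**Silhouette analysis.** Each mask must contain one connected foreground
component of at least 100 pixels; its centroid and second-moment ellipse
drive everything geometric. Geometry class is decided from at least three
views: silhouettes circular within `tol_spherical` (default 0.03, a typical
segmentation-noise level) mean spherical; otherwise the semi-axis along the
near-vertical principal direction — stable across views because the rotation
axis is near vertical — is compared with the horizontal one to separate
oblate from prolate.

**Radii.** The common radius is the median across views of the horizontal
silhouette semi-axis; the distinct radius is the vertical semi-axis at the
reference view. Medians keep single bad segmentations from biasing the
model.

**Reference view and frame.** The frame is initialised where the distinct
axis lies in the image plane: the shortest-minor-axis view for oblate fruit,
the longest-major-axis view for prolate, the first view for spheres (axes
aligned with the view axes). The fruit $y$-axis takes the silhouette
principal direction closer to the image vertical (the expected rotation
axis); at exactly 45 degrees the major axis wins, a documented tie-break. A
nearly circular reference silhouette for a non-spherical label falls back to
a vertical $y$-axis with a warning.

**Pairwise rotation.** The estimator needs visible texture and inter-view
rotations of roughly 20–40 degrees so consecutive views overlap. Harris
corners are detected inside the eroded mask, described by normalised 11x11
intensity patches, matched by mutual-best normalised correlation, and
back-projected to 3D through the spheroid. The rotation is then the
absolute-orientation solution about the fruit centre, made robust by a
seeded 600-sample 3-point consensus search (inlier tolerance 5% of the
largest radius) and refit on the inliers. Fewer than 6 inliers is a failure
signal, and the failed pair is replaced by the geodesic mean of its
neighbours — slip between consecutive frames is smooth enough in practice
that interpolation is the sensible fallback, and the substitution is flagged
in the QC table. Back-projection of both views uses the first view's frame:
exact whenever the fruit spins about its revolution axis (that rotation
leaves the view-space quadric invariant), and a second-order effect
otherwise at the wobble angles the machine produces.

**Chaining.** Frames propagate by multiplying consecutive pairwise
rotations; after every product the result is re-projected onto the nearest
rotation (polar decomposition) whenever orthogonality drift exceeds 1e-9, so
15-link chains keep $\|R^\top R - I\|_\infty < 10^{-6}$.

**Longitude schedule.** Each view's central longitude $L_i$ is the longitude
of the lifted centroid. The known rotation direction means $L_{i+1} > L_i$
must hold; on a wrap, 360 degrees are added to $L_{i+1}$ and all later
views. The map extends `preroll`/`postroll` degrees (default 45) beyond
$L_1$ and $L_N$, filled from the first/last view alone.

**Filling and blending.** Between $L_i$ and $L_{i+1}$ exactly views $i$ and
$i+1$ contribute, with weights linear in longitude
($w_i = (L_{i+1}-\phi)/(L_{i+1}-L_i)$, $w_{i+1} = 1-w_i$, summing to one by
construction) — the two-view bound is what keeps map construction cheap, and
the linear cross-fade is what makes boundaries seamless. A scheduled view
that cannot see a point ($z_i \le 0$, or its sample falls outside the view
mask) is dropped and the surviving weight renormalised to one; if both drop
the pixel stays background. Views are sampled bilinearly (nearest-neighbour
available via `interp` for exactness tests). The angular step defaults to
$\beta = 1/R$ radians for the largest radius $R$, i.e. 1-pixel resolution at
the equator; map dimensions round half away from zero. Latitudes beyond
`lambda_max` (default 60 degrees, where foreshortening makes view pixels
useless) are left as mid-gray bands, like the polar bands of an
uncropped world map; the raster still spans the full pole-to-pole extent so
row indices map linearly to latitude. Column 0 sits at $L_1 - \text{preroll}$,
so early views appear on the left; row 0 is at $+90^\circ$ (north up).

**Measurement.** Every map pixel has a true surface area — the closed form
$r^2\beta(\sin(\lambda+\beta) - \sin\lambda)$ on spheres, a 2-point Gauss
quadrature of the parametrisation's first fundamental form otherwise —
and `surface_fraction()` is the area-weighted ratio of selected to covered
pixels, with columns beyond the first full turn excluded so re-imaged
surface is not counted twice. `find_spots()` recovers dark defects by
thresholding, connected-component labelling, and modulo-360 deduplication.

## The synthetic scene

`synthetic_scene()` + `generate_sequence()` emulate the acquisition: an
orthographically projected spheroid with an equirectangular texture, rotated
about a near-vertical axis (configurable tilt and fruit-axis misalignment to
model wobble) in steps of nominally 30 degrees, 13 views per full turn —
the middle of the machine's operating envelope (12–15 views, 20–40 degrees
per step). Defaults follow the orange application: largest radius 125
pixels. Rendering is flat (texture colour only, no shading) so geometric
correctness is tested in isolation; Gaussian image noise is optional and
seeded. Silhouettes are anti-aliased by 2x2 supersampling, and every pixel
carries its ground-truth $(\phi, \lambda)$, every view its ground-truth
frame and step rotation.

What the generator does *not* emulate — specular highlights, shading
gradients, roller occlusions, soft or wrong segmentation masks, non-spheroid
shapes — bounds what green tests mean: they validate the geometry, the
estimator under ideal photometry, and the map algebra, not robustness to
real-machine imaging artefacts.

Texture kinds: smooth periodic colour `noise` (two octaves, features ~10 px
at the equator — "moderate texture" with matchable keypoints), analytic
`checker`, `spots` (countable dark defects at recorded positions), and
`hemi` (exactly half the surface green, for fraction measurements).

## Numerical choices and degenerate inputs

* Ray–quadric intersection takes the camera-side root; a miss returns `NA`
  (a signal, not an error). Note that on a tilted spheroid $z>0$ alone does
  not imply unoccluded visibility near the limb; the camera-side-root test
  is the exact criterion.
* Ties: reference-view ties break to the earliest view; a 45-degree
  silhouette orientation takes the major axis.
* The consensus sampler and all noise are seeded (`seed` in the config and
  scene), so identical inputs give byte-identical maps.
* A longitude exactly at some $L_i$ gets weight 1 on view $i$ — both segment
  formulas agree there.
* Degenerate sequences: one view builds a pre+post-roll map from that view;
  fewer than three views cannot be auto-classified and are treated as
  spherical unless the class is forced in the config.

## Problem sizes

The validation suite renders 13-view sequences at the application scale
(radius 125 px, ~271x271-px views, ~393x982-px maps) for the end-to-end
checks and radius 40–60 px scenes for unit-level properties; the round-trip
identity is exercised on 10,000 visible points per geometry class at
tolerance 1e-6 degrees.

## Known limitations

* Only spheroids: generic solids of revolution (pears, avocados) are out of
  scope, as are perspective effects, lens distortion and camera calibration.
* The rotation estimator assumes texture; a truly uniform fruit yields
  failure signals and, if no pair succeeds, no map.
* Blending is RGB-wired, though the algebra is channel-count agnostic.
* Radii and rotation are estimated independently; no joint refinement.

## A worked example

```{r example, eval = FALSE}
scene <- synthetic_scene(spheroid_model(125, 125, 125),
                         make_texture("noise", seed = 3),
                         step_angles = rep(30, 12))
b <- generate_sequence(scene)
res <- build_surface_map(b$views, pipeline_config(seed = 1))
res$map
res$qc[, c("pair", "n_inliers", "rmse")]
```
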