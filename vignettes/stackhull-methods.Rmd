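---
title: "Semi-3D morphometrics from focus stacks: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-3D morphometrics from focus stacks: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stackhull)
```

## The measurement problem

Microfossil assemblages — planktonic foraminifera in particular — are
routinely imaged as slide scans: thousands of light shells scattered on a
black slide, photographed through a low-magnification objective as a
z-stack of 31 slices separated by a fixed focal step. A single viewpoint
cannot give full 3D shape, but because each surface point is sharpest in
the slice whose focal plane passes through it, the stack encodes the
*upper* surface: a **semi-3D half-hull**. stackhull turns such stacks into
per-object meshes, volume and surface-area estimates with explicit bounds
for the unobserved back half, assemblage-scale size distributions, and
comparative summaries (consensus dendrograms, tree distances).

The acquisition geometry the package is built around (and which its
synthetic generator reproduces) is: 31 z-slices, a z-step of
$Z = 31.1\ \mu m$ (matched to the depth of field of a 5x objective), and
lateral pixels of $0.975\ \mu m$ that are rescaled to exactly
$1\ \mu m$ before any 3D computation.

## Shape from focus

For every pixel the *focus measure* is the local intensity variance in an
$11 \times 11$ window (truncated at image borders). Across slices the
measure peaks where defocus blur is smallest, so the best-focus slice index

$$b(x, y) = \arg\max_k \operatorname{Var}_{11\times 11}\, I_k(x, y)$$

is an estimate of the surface height in units of the z-step. Ties are
broken toward the lower slice (the slide). The height map stores $b$
rescaled to 8 bits, $H = \operatorname{round}(255\, b / (s - 1))$, and the
physical height is recovered as

$$h = \operatorname{round}\!\left(\frac{H\,(s-1)}{255}\right) Z ,$$

with halves always rounded away from zero. The pair is constructed to
round-trip exactly: every slice index $b \in \{0, \dots, s-1\}$ survives
encoding and decoding unchanged (tested exhaustively for $s = 31$). The
8-bit store is lossy only in that heights are quantized to multiples of
$Z$ — the physical resolution limit of the method in any case.

Two points are worth making explicit:

* **Variance needs texture.** A perfectly uniform surface patch has zero
  variance at every defocus, and its argmax is then decided by the
  tie-break, not by optics. Real foraminifer tests are textured (pores,
  sutures, ornament); the synthetic generator must be textured too (below).
* **Numerical zero.** The windowed variance is computed from summed-area
  tables, whose cancellation residue ($\sim \varepsilon \sum I^2$) would
  otherwise leave microscopic positive "variance" on empty background and
  randomize the argmax there. Variances below that dust scale are clamped
  to an exact zero so flat windows tie deterministically to slice 0.

## From height map to cleaned half-hull

The per-object sequence is:

1. **Rescale** the EDF (extended-depth-of-focus composite) and the height
   map so 1 px = 1 µm, by nearest-neighbour sampling — encoded heights are
   slice indices and must never be interpolated.
2. **Outline masking.** The EDF is thresholded (default 0.18; per-slide
   overrides are normal), the largest 8-connected component is kept, holes
   are filled, and the binary footprint multiplies the height map
   element-wise, deleting all background.
3. **Aperture detection.** Shell apertures image as dark interior holes
   and defeat the focus measure, producing tall spikes. Extracting the
   outline a second time *without* hole filling exposes them: the aperture
   mask is (filled AND NOT unfilled). Those pixels are excluded from the
   initial mesh.
4. **Quartile outlier filter.** One pass over a frozen copy: for each
   valid pixel, the quartiles $Q_1, Q_3$ of the valid heights in an
   $n \times n$ window ($n = 45$ by default) are computed with linear
   interpolation between order statistics (the type-7 estimator); a focal
   value strictly outside $[Q_1, Q_3]$ is replaced by the window mean.
   Invalid/background pixels never enter the statistics — including the
   zeros would drag quartiles toward the background at object edges. A
   single pass over a frozen copy (rather than cascading updates) makes
   the filter order-independent and deterministic. Replacements are means
   of observed values, so the filter can never leave the pre-filter
   height range.
5. **z-level pruning.** Heights are re-quantized to the nearest multiple
   of $Z$; levels holding fewer than 1% of the object's pixels are
   removed (edge noise), and then the bottom-most surviving level is
   dropped (meshes typically retain a rim of background). The bottom drop
   is applied *after* the 1% rule, so "bottom" refers to the cleaned
   object.
6. **Aperture depth.** Aperture pixels are reinstated at the minimum
   height of the cleaned object, i.e. the aperture terminates in a flat
   floor roughly mid-shell. Doing this after pruning means "lowest
   height" is the cleaned minimum.
7. **Triangulation.** One vertex per valid pixel; each fully valid
   $2 \times 2$ block is split into two triangles along the NW–SE
   diagonal. A raster height field admits this exact, deterministic
   triangulation, so no point-cloud meshing heuristics are involved.
   Export formats are ASCII OBJ (1-based faces), OFF (0-based) and an
   x/y/z CSV; full precision is written so read-back is lossless.

## Size: exact top, bounded back

The imaged top hull is measured exactly: volume as the sum of pixel
heights times pixel area, surface area as the summed triangle areas of
the mesh (a literal per-pixel area sum would collapse to the 2D outline
area and carry no relief). The unobserved back half, a column of height
$H$ = the cleaned object's minimum height above the slide, is bracketed by
three completions built from the 2D outline parameters ($A_{2D}$ = area,
$P_{2D}$ = perimeter):

| back shape | volume | surface area |
|---|---|---|
| irregular cylinder | $A_{2D} H$ | $P_{2D} H + A_{2D}$ |
| irregular cone | $A_{2D} H / 3$ | fan of 100 perimeter triangles to an apex at depth $H$ |
| spheroidal dome | $\tfrac12 \cdot \tfrac43 \pi s_x s_y s_z$ | Thomsen's approximation, $k = 1.6$ |

with dome semi-axes $s_x$ = major/2, $s_y$ = minor/2, $s_z = H$. The
cylinder and cone are the attainable extremes, so the spread normalized to
the dome,

$$U = 100\,\frac{E_{cyl} - E_{con}}{E_{dom}} \; [\%],$$

bounds the uncertainty introduced by not seeing the back (computed
separately for volume, always $\ge 0$ since the cone is exactly one third
of the cylinder, and for surface area, which is signed). Conventions worth
noting: the cylinder surface area includes one base cap while the cone is
lateral-only, an asymmetry kept deliberately because those are the
standard printed forms; the "trapeziums" between adjacent perimeter
points and the apex degenerate to triangles, and the triangle fan is the
midpoint-rule limit of that construction; Thomsen's formula is exact when
all three semi-axes coincide, which is what the hemisphere check in the
test-suite exploits.

2D parameters themselves: area is the pixel count, the boundary is traced
with Moore's algorithm and measured as the 8-neighbour chain (diagonal
steps count $\sqrt 2$). That chain overestimates the perimeter of smooth
convex shapes by the classical ~5% digitization bias (it is exact for
axis-aligned rectangles); the bias is documented rather than corrected,
and rugosity — chain perimeter divided by the chain perimeter of the
rasterized convex hull — cancels it by construction, so any convex
footprint scores 1. Axis lengths come from the ellipse with equal
normalized second central moments (with the 1/12 pixel-extent term), the
convention of standard region-properties tooling; aspect ratio is
minor/major and eccentricity follows from the same ellipse. Neither
rugosity nor aspect ratio has a canonical definition in the source
literature for this pipeline; these choices are dimensionless, bounded
and standard.

## The synthetic generator

Every stage above is validated against synthetic stacks with analytic
ground truth. `shape_spec()` describes convex shell-like objects
(hemispheroids, spheres resting on the plane, cones, blocks, terraced
blocks for z-level logic), optionally with a circular aperture rendered
dark. `make_heightfield()` samples the analytic surface at pixel centres
and records closed-form volumes/areas. `render_zstack()` implements the
defocus model: slice $k$ is the focal plane at height $kZ$; each footprint
pixel is the object's albedo blurred with an isotropic Gaussian of spread
$\sigma = c\,\lvert h - kZ \rvert$ (blur coefficient $c = 0.05$ px/µm by
default — mild, resolvable blur for this geometry), plus i.i.d. Gaussian
noise (default sd 0.01 in intensity units, a conservative stand-in for
sensor noise); background pixels are exactly 0 before noise. Blur is
evaluated by interpolating between a bank of Fourier-domain blurs on a
defocus grid of $Z/2$, which keeps the render $O(\text{slices} + \text{bank})$
FFTs rather than per-pixel convolutions.

Because shape-from-focus needs texture, the generator multiplies the
albedo by a seeded speckle field (amplitude 0.35, correlation length
1.5 px) — emulating the pore-and-ornament texture of real tests. An
optional "smear" pathology (a disc rendered at one fixed blur in every
slice, so no slice is sharpest) reproduces the focus-stacking failure mode
seen on real material and is available for provoking the outlier filter in
tests. Everything is deterministic given a seed, and the RNG state of the
caller is left untouched.

What the generator does *not* emulate: physically accurate point-spread
functions, refraction through calcite walls, tiling seams, glare, mounting
tilt, or inter-frame brightness drift. Passing tests therefore demonstrate
the correctness of the extraction machinery under a faithful defocus
geometry, not robustness to every acquisition pathology of real slides.

## Validation conditions and problem sizes

The study conditions mirrored throughout the tests are the acquisition
geometry above. The headline end-to-end check renders seven spheres on
the plane with diameters 300–900 µm (the working size range of adult
planktonic foraminifera; the segmentation size filter is 125–2000 µm),
runs the full pipeline, and requires the extracted maximum height of
every object to sit within 7.67% of the known diameter — the tolerance
established for this approach with spherical *Orbulina universa* shells.
Under the default optics the observed deviations are dominated by height
quantization ($Z/2$ at worst, i.e. 5.2% at 300 µm, 1.7% at 900 µm) and
come out well inside the bound (≤ ~4%). Unit fixtures use radii of
60–300 µm and canvases up to ~660 px so the full suite stays fast; the
sliding-window filter is exercised at its default $n = 45$ throughout.

## Comparative machinery

Downstream of morphometrics the package provides the standard comparison
stack: species-mean score matrices; Euclidean distances, or Jaccard
distances over one-hot-encoded categorical ecological traits (a bundled
15-species table of symbiont type, habitat depth and geographical range
ships with the package); agglomerative clustering under Ward, single,
complete, average and McQuitty linkages (Ward defaults to the classic
unsquared-distance Lance–Williams recurrence, with the squared variant
behind a flag, because published analyses of this kind predate the
squared-distance default); strict >50% majority-rule consensus; and the
path-difference metric between unrooted topologies — the Euclidean
distance between vectors of leaf-pair path lengths in edges. Path
difference is defined for binary trees, so multifurcating consensus
topologies are resolved uniformly at random, 2000 replicates by default,
and the mean is reported. Clustering and path difference are verified in
the test suite against brute-force oracles (direct Lance–Williams
agglomeration; BFS path counting over all 15 five-leaf unrooted
topologies).

Two choices here are genuinely open and were fixed as follows: trait
coding for Jaccard uses one indicator column per trait level (the
literature using this pipeline does not state its coding, so distances
derived from it may differ from published tables even when the procedure
matches); and consensus operates on rooted dendrogram clades, the natural
reading for dendrograms, with ties at exactly 50% excluded.

## Known limitations

* Heights are quantized to the z-step; nothing finer than $Z$ is
  recoverable, and the relative error budget is dominated by $Z/2$ for
  small objects.
* The bottom-level drop removes a real annulus of the object along with
  the background rim; for small, steep objects that annulus is a
  noticeable fraction of the footprint (documented in the pipeline
  tests). Base heights are accordingly biased upward.
* The chain-code perimeter bias (~5% on smooth convex outlines) feeds
  $P_{2D}$ and hence the cylinder surface area.
* Aperture detection is the literal filled-minus-unfilled rule, so any
  interior pixel falling below the outline threshold — including isolated
  dark speckle on a heavily textured surface — is treated as aperture and
  floored. Enable `mask_aperture` for aperture-bearing material; leave it
  off for objects known to lack one.
* Touching objects are not split (no watershed); glare is handled only by
  per-slide threshold tuning.
* The EDF here is the argmax-slice composite, not a proprietary
  focus-stacking engine's output; brightness correction between frames
  and contrast-threshold heuristics are out of scope.
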