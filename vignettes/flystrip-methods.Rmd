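---
title: "Quantifying gene expression boundaries from embryo images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gene expression boundaries from embryo images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flystrip)
```

## The problem

Colorimetric whole-mount in situ hybridisation (WMISH) stains the mRNA of a
gene of interest in intact fly embryos; enzymatic precipitates (purple
NBT/BCIP or red FastRed) render spatial expression visible in ordinary
bright-field microscopy. Segmentation genes of dipterans — maternal
gradients and the gap gene system in particular — are expressed in broad,
*graded* domains along the antero-posterior (A–P) axis of the blastoderm,
and what a network-level analysis needs from each embryo is not a binary
on/off pattern but the *position of each expression domain boundary*, in a
coordinate system comparable across embryos, stages and species.

`flystrip` implements a medium-throughput processing chain from raw
micrographs to aggregated boundary dynamics:

1. **Segmentation** — a binary embryo mask from the 10x DIC image.
2. **Orientation** — rotate so the A–P axis is horizontal, crop to the
   mask; flips to the anterior-left / dorsal-up convention are manual
   inputs (a batch CSV), because automated A–P/D–V polarity calls on
   blastoderm embryos are unreliable.
3. **Profile extraction** — mean per-channel intensity in a strip covering
   10% of the dorso-ventral axis around a spline-smoothed midline, indexed
   by percent egg length (%EL; 0 = anterior).
4. **Boundary fitting** — each domain edge ("slope") modelled as a cubic
   spline clamped to zero slope at its end knots; window placement is the
   one deliberately manual step, supplied per embryo as a table.
5. **Aggregation** — median boundaries per gene/slope/time class,
   variability datasets and space-time tables of boundary mid-points.

A synthetic image generator with exact ground truth stands in for real
micrographs throughout the tests.

## The mask pipeline

The mask is produced by a fixed 13-operation sequence on the DIC image,
recorded stage by stage in the returned object (14 stored intermediates,
since the final small-blob removal repeats operation 11): grey conversion,
gamma correction, inversion, Sobel edge magnitude, binarisation, two
dilations, border-blob removal, two further dilations, hole filling,
border-blob removal, small-blob removal, Gaussian smoothing, re-binarisation
and a final small-blob removal.

The tunable parameters, with defaults:

| parameter | default | units | role |
|---|---|---|---|
| `gamma` | 0.08 | – | contrast compression before edge detection; a very small exponent flattens bright background texture while keeping dark embryo outlines steep |
| `edge_threshold` | 6 | intensity | cutoff on the Sobel magnitude (`<=` goes to background) |
| `beta` | 13.0 | – | blobs smaller than (image area)/`beta` are artefacts; decrease to remove bigger debris, increase for small-bodied species so the embryo itself is not discarded |
| `blur_sigma` | 31 | px | Gaussian that smooths the mask edge |
| `blur_accuracy` | 1e-3 | – | kernel truncation: the omitted tail mass per axis stays below this |
| `post_blur_threshold` | 145 | intensity | re-binarisation after smoothing; being above 128 it slightly erodes the smoothed blob |

Numerical conventions that the original description leaves open, fixed here
once: grey conversion is the unweighted channel mean (weights are
configurable); Sobel borders are handled by edge replication so the image
frame itself produces no edges; blobs are 8-connected and dilation uses the
3×3 square element; holes are background components under 4-connectivity
(the topological dual); the smoothing step returns *continuous* values —
blurring in float space — because re-quantising to 8 bits would destroy
faint responses (an impulse blurred at sigma 31 peaks far below one
intensity unit) and the subsequent threshold is the only consumer.
Images smaller than 3×3 are rejected outright. If several blobs survive the
area cut, all are kept, the condition is recorded, and the mask quality is
`"not good"`; the controlled quality vocabulary (`good`/`ok`/`not good`)
follows the annotation scheme.

## Orientation

The A–P axis angle comes from the central second moments of the foreground:
the principal-axis direction `atan2(2*mu11, mu20 - mu02) / 2`, in
`(-90, 90]` degrees. Rotation (by the negative angle, about the image
centre) uses bilinear interpolation; the mask is re-binarised at 128
afterwards, and everything is cropped to the rotated mask's tight bounding
box. An isotropic mask has no major axis; it yields 0 degrees with a
warning rather than an error, since circular-ish debris still crops
correctly. Rotating about the image centre (not the centroid) is a
convention choice; the subsequent crop makes the two equivalent up to
border clipping.

## Midline, strip, and profiles

The midline is the skeleton of the mask (Zhang–Suen thinning), reduced to
its **main branch**: the longest geodesic between skeleton endpoints, with
diagonal steps weighted sqrt(2). Five knots are placed at arc-length
fractions 0, 1/4, 1/2, 3/4, 1 of that branch — "equidistant" is
under-specified, and including the endpoints maximises axis coverage before
any extrapolation. A natural cubic spline interpolates the knots; beyond
the outer knots the curve follows the quadratic Lagrange polynomial through
the three outermost knots on that side, reaching the mask borders so the
entire A–P axis is covered (quadratic is the lowest degree that carries
midline curvature without inviting oscillation). Manual knot dragging in an
interactive tool becomes an optional knot-override table.

The extraction strip spans 10% of the dorso-ventral axis — 5% above and
below the midline — with the minor-axis length measured as the maximal
vertical extent of the oriented mask (exact for an oriented embryo, and
robust because it needs no model fit). Per pixel column, the mean R, G and
B intensities over the band form the expression profile; columns map
linearly to %EL over the mask's horizontal extent.

Stain signals are linear combinations of channels: `nbt = red` for
NBT/BCIP and `fastred = green - red` (clipped at zero, since the
difference can go slightly negative in unstained noise) for FastRed. Dark
precipitate in transmitted light should *lower* a channel; whether the
original display convention inverts is unknowable from the description, so
`stain_signal(..., invert = TRUE)` reports `255 - signal`, and the
synthetic generator emits images consistent with the uninverted formulas by
default.

## Boundary splines

A boundary is parameterised by its outer knot `x0` (signal first
distinguishable from background) and inner knot `x2` (plateau expression),
both placed by the analyst. The middle knot sits at the midpoint
`x1 = min(x0, x2) + |x2 - x0|/2` — taking the published half-distance
formula literally would put `x1` outside the window for most placements,
while the same source calls `x1` the boundary "mid-point" throughout its
analyses, so the midpoint reading is implemented — with `y1` read from the
profile at `x1` (nearest sample; profiles are per-column discrete).

The spline itself is two cubic Hermite pieces joined C1 at `x1`, with the
first derivative clamped to zero at `x0` and `x2`. A single C2 cubic
through three knots with both end slopes clamped is an alternative reading,
but it is not shape-preserving: for uneven monotone knot values it
overshoots below the outer knot. The midknot slope here is the
span-weighted average of the two secants, limited in the Fritsch–Carlson
manner, which guarantees a monotone curve through monotone knots — the
shape a graded expression boundary is assumed to have.

`suggest_window()` is advisory plumbing that encodes the manual placement
guidelines (inner edge where the signal levels off, outer edge where it
sinks into background): candidate `x2` at the first position reaching 90%
of the plateau, candidate `x0` at the last position below the background
mean + 2 SD (background estimated from the lowest quartile of the smoothed
signal). The thresholds are conveniences, not claims; suggestions are never
auto-committed.

## Aggregation

Median boundaries take the median `x0` and `x2` (and y values)
independently across a group sharing gene, slope id, polarity and time
class, with the even-count median as the mean of the central order
statistics; the middle knot is re-derived as the midpoint of the median
endpoints and the spline refitted on the median knots (re-reading `y1` from
a "median profile" would require a profile registration step the data model
does not assume). Variability datasets evaluate individual and/or median
splines on a grid with per-curve min–max normalisation — absolute intensity
comparisons across enzymatically stained embryos are explicitly untrusted,
so only [0, 1]-scaled shapes are displayed, and multi-gene selections are
restricted to medians. Space-time tables list the mid-point `x1` of each
median boundary ordered by time class.

Time classes are a validated vocabulary (`C1`–`C13`, `C14A`, and
`C14A_T1`–`C14A_T8`, the eight 6–7-minute subdivisions of cycle 14A);
classification itself is a manual, expert task and is deliberately not
automated here.

## The synthetic generator

`render_embryo()` emulates the four-image acquisition of one embryo:

* **DIC**: an ovoid body (superellipse, exponent 2.5 — blastoderm embryos
  have blunt poles, not pointed ellipse tips) with a dark outline ring
  centred 0.5 px inside the true boundary (the cortical shadow belongs to
  the embryo), mild interior texture, on an even background.
* **Bright-field**: per-domain logistic intensity ramps
  `plateau * (sigm((x-a)/s) - sigm((x-b)/s))` written into the red channel
  (NBT) or as green-over-red excess (FastRed), over a faint embryo body
  shading that cancels in the FastRed difference.
* **Nuclear counterstain**: Gaussian dots at uniform positions inside the
  body; **membrane detail**: a high-magnification texture stand-in.

Defaults are one choice of realistic study conditions: a 960×720 px scene,
semi-axes 300×120 px (roughly a 500 µm embryo at binned 10x wide-field
sampling), background 40, noise SD 5, one NBT domain spanning 40–60 %EL
with steepness 1.5 %EL and plateau 150. Sensor noise is *band-limited*:
white noise smoothed at the optical scale (2 px) and rescaled to the
requested per-pixel SD, because wide-field optics and demosaicing leave no
pixel-scale white noise in real micrographs; i.i.d. pixel noise at
comparable SD is an unphysical worst case that no edge-based segmentation
(including this one) survives. Rendering is deterministic given the spec;
batches derive one seed per embryo.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: uneven illumination, out-of-focus neighbours
away from the border, yolk autofluorescence, staining saturation and
nonlinear signal amplification, and genuine embryo shape variation. The
generator's purpose is exact ground truth for the geometry and
densitometry of the chain, not photorealism.

## Numerical behaviour on the fixtures

With the default study conditions the chain recovers the ground-truth mask
with IoU above 0.98 (noiseless) and above 0.95 with noise SD 10 or at
rotations up to 80 degrees; residual boundary displacement is dominated by
the direction-dependence of the square structuring element (four dilations
grow 4·(|cos φ|+|sin φ|) px along a boundary normal at angle φ, against an
isotropic ~5.4 px erosion by the smooth-and-rethreshold step) plus pole
erosion where the outline curvature is comparable to the 31 px blur.
Principal-axis angles of fixture ellipses are recovered within 0.5 degrees
for true angles −60…60; half-maximum boundary positions of extracted
signals land within 1 %EL (noiseless) and 2 %EL (noise SD 10) of the
programmed domain edges.

Problem sizes used in the shipped tests — 4×4 exhaustive morphology
enumeration (65,536 cases against a brute-force flood-fill oracle), 20
seeds per segmentation condition, six boundary-recovery conditions — are
the package's choice of a thorough desk-scale regression suite.

## Storage and interfaces

The batch store is a directory of plain CSV tables (`embryos`, `params`,
`profiles`, `boundaries`, `log`) plus a JSON manifest — an embedded SQL
file would add a dependency without adding capability at desk scale, and
plain text keeps every processing parameter diffable and recoverable
(provenance completeness: gamma, beta, rotation angle and crop box are
stored per embryo). The command-line entry point
(`inst/cli/flystrip`) is a thin dispatcher over exported functions with
subcommands `add`, `run`, `slopes`, `analyze`/`export` and `render`;
manual steps arrive as CSV tables (flips, boundary windows, knot
overrides). Plots export as SVG and PDF.

## Known limitations

* Only one embryo per scene is supported; crowded scenes and
  machine-learning shape priors are out of scope.
* A–P/D–V polarity (flips) and developmental staging are manual inputs.
* Relative expression *levels* across domains are not measured — signal
  amplification is potentially nonlinear and saturation in dense
  precipitate is undetectable — so all intensities are per-curve
  normalised.
* The NBT channel convention follows the stated extraction formula; for
  real transmitted-light data where stain lowers the red channel, use
  `invert = TRUE` when deriving signals.
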