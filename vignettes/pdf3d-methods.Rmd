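---
title: "Methods: building interactive 3-d PDF figures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building interactive 3-d PDF figures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdf3d)
```

This vignette documents the models, algorithms, numerical choices and known
limitations behind `pdf3d`. The package turns surface meshes and volumetric
images into single-file PDF documents carrying an interactive 3-d annotation
alongside an ordinary raster poster figure.

## The model tree

Every exportable piece of geometry belongs to exactly one group of a named,
acyclic scene graph. Viewers expose this tree to the reader, who can toggle
branches on and off; views files and the control script address nodes by
name. Names must therefore be unique, so `register_group()` appends a
1-based decimal serial per short name: registering `"cortex"` twice yields
`"cortex1"` and `"cortex2"`. The suffix scheme is the simplest deterministic
realisation of a serialized-suffix rule; the full names are recoverable
programmatically and are written to a node-map file (`s2direct.map` dialect:
one `short<TAB>full.dotted.path` line per group, LF endings, `"."` as the
path separator). Payloads added before any group is registered attach to an
implicit root group named `S2ROOT1`.

Billboards are textured quads that always face the reader. At display time
the control script re-orients them before every redraw; `orient_billboards()`
implements the same operation for testing and poster generation: the minimal
(roll-free) rotation about the quad centre taking the quad normal onto the
centre-to-camera direction. Centres, edge lengths and areas are preserved
exactly; the roll-free choice keeps labels upright without a preferred up
vector.

## Mesh compression

The internal mesh representation is deliberately naive: a *facet soup* of
independent triangles and quads, each with its own vertices, normals, colour
and opacity. This is flexible for readers and generators but wasteful to
store — in a closed surface a vertex is shared by three or four facets.

`build_indexed_mesh()` deduplicates vertex records on the pair (position,
normal). The default tolerance is 0, i.e. exact bitwise agreement (negative
zero folded onto zero); an optional `position_tol` quantizes both position
and normal to a grid of that pitch before matching, which welds vertices that
differ by floating-point noise from upstream tools. Matching includes the
normal deliberately: a hard crease needs distinct records on each side, while
smooth per-vertex normals (exact analytic normals in the synthetic
generators, `vn` records in OBJ) make shared vertices collapse. Expansion of
the index lists reproduces the input facets exactly, which is asserted
against a brute-force quadratic dedupe in the tests.

Colour quantization reuses the same machinery with a relaxed colour
criterion. `group_facets_by_colour()` makes one greedy sequential pass: a
facet joins the first existing mesh whose *representative* colour — the
colour of the facet that started that mesh, not a running mean — lies within
a threshold in Euclidean RGB distance (and whose opacity matches exactly);
otherwise it starts a new mesh. Keeping the representative fixed makes the
pass order-deterministic and the partition reproducible; ties go to the
first-created mesh. With threshold 0 the pass degenerates to the exact-colour
partition, and increasing the threshold can only merge groups, never split
them, so the mesh count is monotone non-increasing. The default CLI threshold
of 0.05 is this package's choice of a conservatively small distance in the
unit RGB cube; no canonical value exists. Perceptual colour spaces and global
clustering (k-means and friends) are deliberately out of scope — the pass is
a quantization, not an optimisation.

## Texture encoding

Textures are held as 8-bit-per-channel RGBA (values snapped to the 8-bit grid
on construction, which is the precision every container stores). The encoder
picks its container by a strict opacity rule: a texture is *opaque* only if
no pixel has alpha below 1, and opaque textures become JPEG streams (default
quality 90 — a conventional high-quality setting; the smooth surface
textures JPEG is used for show mean per-channel error well under 0.05 at this
setting). A single pixel at alpha 0.99 switches the texture to the
transparent path.

Transparent textures are reduced to at most 256 distinct RGBA values:
median-cut box subdivision selects the palette (alpha weighted equally with
R, G, B), then Floyd–Steinberg error diffusion assigns pixels in plain
raster order with the classic 7/16, 3/16, 5/16, 1/16 weights (no serpentine
traversal — a fixed, documented choice). When the input already has no more
colours than the ceiling the palette is exact and the encoding lossless,
with dithering skipped; this makes slice textures produced through the
greyscale colourmap (at most 256 distinct values by construction)
bit-faithful and keeps tests deterministic. Distinct colours are counted as
distinct RGBA tuples, so alpha variants of one RGB count separately.

The palette image is written as a true indexed PNG (colour type 3, palette
in `PLTE`, per-entry alpha in `tRNS`, filter-0 scanlines). The installed
`png` package only writes truecolour PNGs, so this small encoder is part of
the package; decoding in tests goes through `png::readPNG`, an independent
route. One palette index per pixel plus zlib compression is what delivers
the ~50%-or-better saving versus raw 32-bit-per-pixel bitmaps that
`savings_ratio()` reports (`1 − bytes/(w·h·4)`, negative for pathological
noise).

## Volumes and slice-based rendering

Volumes travel in the XRW dialect: magic `"XRW2"`, three little-endian
uint32 dims, three little-endian float32 spacings, then `nx·ny·nz`
little-endian uint16 samples, x fastest. Write∘read is bit-exact on dims and
samples. `stack_to_volume()` maps slice `k` of an image stack to plane
`z = k` and rescales intensities affinely so the global minimum hits 0 and
the maximum 65535 (constant stacks map to 0).

The transfer function maps normalised intensity to colour through a named
map (`greyscale`; `hotiron` as a black→red→yellow→white piecewise-linear
ramp with breakpoints at 0, 1/3, 2/3, 1 — the package's fixed definition of
a conventionally-named map), an interpolated table, or a user function, and
to opacity through a linear ramp over an intensity window reaching
`alpha_max` — non-decreasing in intensity by construction. Pre-shading here
means transfer-function application only; no directional lighting is baked
into slice textures.

Because the PDF 3-d extension lacks 3-d textures, view-dependent 2-d
texturing is used instead: three orthogonal sets of RGBA textures, one per
voxel plane per axis (in-plane axes follow the cyclic order x→(y,z),
y→(z,x), z→(x,y); no resampling). Only the set whose axis is most aligned
with the camera (largest |dot|, ties broken x<y<z, invariant under direction
negation) is shown at a time.

For a sight-line crossing `n` slices of uniform alpha `α`, source-over
blending accumulates `A = 1 − (1 − α)^n` — exponential, not linear. An
anisotropic volume therefore composites to different overall opacity along
different axes, and the switch between slice sets produces a visible jump.
`rescale_opacity()` applies `α' = 1 − (1 − α)^f` per texel with default
factors `f = max(dims)/dims`, the axis-length ratios: with these defaults a
uniform volume composites to *identical* opacity along all three axes, and
the test suite asserts agreement within 1% for an anisotropic uniform
phantom. The exponent form is chosen precisely because the accumulation is
exponential — a linear `α·f` rescaling (provided behind `method = "linear"`
for comparison) cannot equalize, and a test demonstrates that it does not.
The factors remain user-settable for manual fine-tuning on real data, where
content is not uniform and the best-looking factors can deviate from the
axis ratios. `composite_slices()`, the orthographic source-over compositor,
exists primarily as the measurement oracle for these properties.

## Views

`default_presets()` supplies the seven standard views bound to keys 1–7:
front/back/left/right/top/bottom perspective along the coordinate axes plus
an oblique perspective along the cube diagonal. The views file dialect is
block-structured plain text (`VIEW=…`/`END`, keys `C2C`, `ROO`, `ROLL`,
`PROJECTION`, `LIGHTS`, and repeated `PART=` + `VISIBLE=` pairs with
optional `OPACITY=`). Numbers serialize with 17 significant digits so both
`parse(format(x))` and `format(parse(t))` are exact identities; an
already-unit camera direction is left bit-identical rather than
re-normalised. The grammar is this package's own dialect, self-consistent
but not claimed byte-compatible with any external view-capture tool.
`apply_view()` resolves part names against the model tree (full name or
dotted path), defaults every node to visible, and errors on unknown names
rather than silently ignoring them.

## Scene payload and PDF embedding

The scene container is a deterministic binary serialization of the model
tree: magic, group records (short/full/parent names, in registration order),
then typed payload records with little-endian float32 coordinates, and
textures as their encoded JPEG/PNG byte streams. Textures attached to
billboard and textured-facet payloads are encoded at payload construction,
so identical trees always produce byte-identical payloads and texture
digests are stable. No public reference reader exists for the scene format
commercial PDF tools embed, so the authoritative automated check is the
package's own `read_prc()` round trip — structural equality on names,
order, counts, colours (exact), coordinates (float32 precision) and texture
bytes (exact) over fuzzed scenes — plus structural probes of the finished
PDF. Rendering in a 3-d-capable viewer remains a manual check by nature:
no such renderer can run in an automated test environment.

`embed_pdf()` writes a single-page PDF 1.7 document by hand: one 3-d
annotation whose unfiltered stream holds the payload verbatim (hence the
byte-equality probe), the poster image as both the annotation's normal
appearance and the page content (so any viewer and print show it), one view
dictionary per preset carrying camera-to-world matrix, orbit distance,
projection, lighting scheme and per-node visibility, and the control script
attached to run on instantiation. Activation defaults to click — the
conservative choice, since the poster is shown until the reader opts in;
`activation = "auto"` activates on page open. No timestamps or random
identifiers are emitted, so output is byte-deterministic. The structural
probe (`read_pdf_objects()`/`probe_pdf3d()`) is written independently of the
writer — it scans object frames and reads streams via their `/Length`
entries — because no PDF-parsing library is available as a dependency.

Transparent multi-facet meshes are stored as indexed meshes by default (the
fast path) with a warning: viewers sort transparent facets per payload, so a
transparent indexed mesh can render with incorrect depth ordering against
other transparent geometry. The documented work-around,
`transparent_as_facets = TRUE`, stores such meshes as unstructured facet
lists — larger and slower, but sortable per facet.

## Validation imagery

`difference_image()` computes per-channel absolute differences, converts to
greyscale with Rec. 601 luminance weights (0.299, 0.587, 0.114 — the
conventional weights; the exact conversion used by interactive photo editors
is not published), and smooths with a radius-1 box mean whose border pixels
average their in-bounds neighbours, suppressing sub-pixel co-registration
artefacts. `edge_overlay()` uses Sobel gradient magnitude with
replicate-edge padding, thresholded at any non-zero gradient by default (the
analogue of selecting all non-white pixels of an edge-filtered image), and
paints the two masks in two colours with the second drawn over the first.
Inputs are assumed co-registered; alignment search is out of scope. Both
procedures aid qualitative comparison only.

## Synthetic data

The generators stand in for acquired data so that the entire pipeline is
testable offline and deterministically. `synth_volume()` provides a Gaussian
blob (argmax at the centre voxel) and a Gaussian-profiled spherical shell
(maximal on the stated radius), both normalised to the 16-bit scale, with
optional seeded uniform noise. `synth_mesh()` provides a UV sphere (quads
with polar triangle fans, vertices on the sphere to 1e-6, exact analytic
per-vertex normals), a closed quad torus (every edge shared by exactly two
facets), and a two-part anatomy scene (opaque core, translucent shell) of
the shape a segmented-anatomy figure uses. `synth_texture()` produces a
smooth RGBA gradient with radial alpha falloff — thousands of distinct
colours, the worst case for palette quantization and the shape of a typical
volume-rendering slice.

What the synthetic inputs do *not* emulate: anatomical structure, scanner
noise characteristics, registration error, or mesh defects (holes,
non-manifold edges, degenerate facets) found in real segmentations. Passing
tests certify the pipeline's algebra and formats, not robustness to
malformed real-world inputs beyond the explicit error contracts.

## Problem sizes and defaults

The test suite and the acceptance script run at desk scale by choice:
volumes up to 24×32×40 voxels, meshes up to ~2200 facets, textures up to
256×256, fuzzing at 5–10 repetitions per property. These sizes exercise
every code path (all three slice axes distinct, quantization above and below
the palette ceiling, quads and triangles, nested groups) while keeping a
full run around half a minute. Defaults chosen once and documented: JPEG
quality 90; palette ceiling 256; colour-grouping threshold 0.05; dedupe
tolerance 0; alpha window (0.05, 1) with `alpha_max` 0.8 in `xrw2pdf` (a
mild noise floor and slight global translucency, reasonable for looking
*into* a volume); poster defaults to the composite of the slice set facing
the oblique view.
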