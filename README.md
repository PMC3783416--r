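# pdf3d — interactive 3-d scientific figures embedded in PDF documents

Most journals and readers exchange figures as static, 2-d projections, even
when the underlying data — MR volumes, segmented anatomy, cortical surfaces,
stacked microscope sections — is intrinsically 3-dimensional. The PDF format
itself supports fully interactive 3-d annotations: a reader with a 3-d-capable
viewer can rotate the model, toggle named parts of the scene on and off, and
recall predefined views, while every other viewer (and print) falls back to an
ordinary raster "poster" figure. `pdf3d` is an R toolchain that takes surface
meshes and volumetric images all the way to such a self-contained,
single-file, interactive 3-d PDF figure.

## What the package does

**Model tree.** All geometry is organised in a named, hierarchical scene
graph. Group names receive a serial suffix guaranteeing uniqueness
(`register_group(tree, "cortex")` → `"cortex1"`, `"cortex2"`, …), so views
and scripts can address parts of the scene reliably; the short-name → full
dotted-path mapping is written to a companion `s2direct.map` file.

**Surface mesh and colour compression.** Mesh readers (STL ASCII/binary,
Wavefront OBJ, FreeSurfer ASCII surfaces and weight files) produce a *facet
soup* — independent 3-/4-vertex facets, each with its own vertices, normals,
colour and opacity. For export this is compressed: facets are grouped into
single-colour meshes by a greedy quantization pass (a facet joins the first
mesh whose representative colour is within a chosen Euclidean RGB distance),
and each group is converted to a *vertex-indexed mesh* in which a vertex
record (position + normal) shared by several facets — typically three or four
in a closed surface — is stored once, and the colour once per mesh. Indexed
meshes are also substantially faster to load and render in PDF viewers than
loose facets.

**Texture compression.** Entirely opaque textures are stored as JPEG.
Textures with any transparent pixel are reduced to ≤ 256 distinct RGBA
colours (median-cut palette + Floyd–Steinberg error diffusion) and stored as
an indexed palette PNG — roughly half the size of a raw 32-bit-per-pixel
bitmap or better.

**Slice-based volume rendering.** Volumes travel in a minimal normalised
16-bit container (XRW: magic, dims, spacings, uint16 samples). A transfer
function maps intensity to colour (greyscale or hot-iron, or user tables) and
to opacity over a window. Because PDF's 3-d extension has no 3-d textures,
the renderer stores *three* orthogonal sets of pre-shaded RGBA slice
textures; at display time a script shows only the set most aligned with the
camera. Composited opacity accumulates exponentially along sight-lines
(`A = 1 − (1 − α)^n` for `n` uniform slices), so for anisotropic volumes the
three sets would render with visibly different density and the transitions
between them jump. `rescale_opacity()` equalizes this with per-texel
`α' = 1 − (1 − α)^f`, defaulting the factors `f` to the axis-length ratios,
which makes the per-axis composited opacity of a uniform volume exactly
equal.

**Views and export.** Seven standard presets (front/back/left/right/top/
bottom/oblique perspective, bound to keys 1–7) plus a plain-text views
dialect (`s2views.txt`) with per-node `VISIBLE` overrides. The scene is
serialized to a compact deterministic binary payload and embedded in a
single-page PDF 1.7 document as a 3-d annotation with a poster image, one
view dictionary per preset, click- or page-open activation, and an attached
control script. An in-package structural PDF probe and payload reader verify
round trips.

**Validation imagery.** `difference_image()` (per-channel absolute
difference → Rec. 601 greyscale → radius-1 box blur) and `edge_overlay()`
(Sobel edge masks painted in two colours) reproduce the side-by-side
comparison procedures used to check 3-d PDF renderings against other
software. These are qualitative aids, not quantitative metrics.

## Worked example

```r
library(pdf3d)

# two-part synthetic anatomy: a translucent shell around an opaque core
parts <- synth_mesh("two_part_anatomy", n_theta = 24, n_phi = 24)
write_stl_ascii(parts$shell, "shell.stl")
write_stl_ascii(parts$core,  "core.stl")
s2stl(c("shell.stl:0.9,0.85,0.7:0.35", "core.stl:0.85,0.15,0.15:1"),
      "anatomy.pdf", transparent_as_facets = TRUE)
#> s2stl: 2208 facets -> 2 meshes, vertex records 6624 -> 4512, payload 166889 bytes

# volume rendering of a synthetic phantom
v <- synth_volume("gaussian_blob", dims = c(24, 32, 40), noise = 0.05)
write_xrw(v, "blob.xrw")
xrw2pdf("blob.xrw", "blob.pdf", colourmap = "hotiron")
#> xrw2pdf: 96 slice textures in 3 sets, payload 185758 bytes
```

The first call reads the two STL files, shades them with the nominated
colour and opacity, quantizes colours and builds vertex-indexed meshes
(6624 facet-soup vertex records collapse to 4512 — STL carries flat facet
normals; formats with smooth per-vertex normals such as OBJ `vn` records
compress markedly further), and writes `anatomy.pdf` with the two named
groups, plus `anatomy.map` (node names) and `anatomy_views.txt` (the seven
presets). The second builds 24 + 32 + 40 = 96 pre-shaded slice textures in
three orthogonal sets with axis-ratio opacity equalization and embeds them
the same way. Both PDFs show their poster image in any viewer; a 3-d-capable
viewer activates the interactive scene on click.

Command-line wrappers for `stack2xrw`, `xrw2pdf`, `s2stl` and
`fig3d-validate` are installed under `inst/scripts/`.

## Limitations

- Transparent multi-facet meshes stored as indexed meshes can sort
  incorrectly against other transparent geometry in viewers; the
  `transparent_as_facets` option stores them as unstructured facet lists
  instead (larger, but correctly sortable). See the methods vignette.
- The binary scene payload is this package's own deterministic dialect,
  verified by its in-package reader; byte-compatibility with any external
  tool's scene container is not claimed.
- Only 3-d-capable PDF viewers render the interactive content; everything
  else shows the poster image.
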