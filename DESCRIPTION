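Package: pdf3d
Title: Interactive 3-D Figures Embedded in PDF Documents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns scientific 3-d data (surface meshes and volumetric
    images) into interactive 3-d figures embedded in PDF files. Builds a
    named hierarchical model tree of geometry, compresses facet soups into
    per-colour vertex-indexed meshes, encodes textures (JPEG for opaque,
    palette PNG with Floyd-Steinberg dithering for transparent), performs
    slice-based pre-shaded volume rendering with opacity equalization from
    16-bit normalised volumes (the XRW dialect), manages predefined camera
    views with per-node visibility, serialises the scene to a compact
    binary payload, and writes a single-page PDF with a 3-d annotation,
    poster image, predefined views and attached script. Also provides the
    image-comparison procedures (smoothed difference images, edge overlays)
    used to validate renderings, and deterministic synthetic volume and
    mesh generators.
License: MIT
Encoding: UTF-8
Imports:
    jpeg,
    png,
    tiff,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
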