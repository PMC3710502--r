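Package: pointworlds
Title: Multi-World 3D Point Cloud Scenes with Class Overlays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Read, validate, convert and render the two-file model for 3D
    biological point data: a "dataset" file holding an ordered set of 3D
    points (optionally chained into a polyline, as for protein backbones)
    and an "information layer" file assigning each point to one of a
    declared number of classes (for example gene-expression clusters of
    cells). Both file families are supported in JSON, XML and CSV dialects
    with explicit lossiness warnings, strict validation and byte-stable
    canonical writers. Scenes of up to four linked "worlds" bind datasets
    to layers with per-class visibility and colour, and render either to a
    single self-contained interactive HTML document or to a static PNG.
    Importers convert coordinate tables, categorical label vectors and
    PDB-format C-alpha traces into the two-file model, and a synthetic
    generator produces clustered 3D cell-map fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    xml2,
    bio3d,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    png,
    withr
Config/testthat/edition: 3
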