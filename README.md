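# pointworlds

Multi-world 3D point-cloud scenes with per-class overlays, for biologists
who have spatial data — a map of cells in a tissue, principal-component
scores, a protein backbone — and per-point annotations to drape over it.

## The data model

Everything is built from two small file families:

- **dataset file** — a named, ordered set of N points
  (x<sub>i</sub>, y<sub>i</sub>, z<sub>i</sub>), i = 1..N, with a boolean
  `chain` flag. Chained datasets are drawn as a polyline through the
  points in file order (N − 1 segments, the natural view of a Cα
  backbone); unchained datasets are independent particles (a cell
  population).
- **information layer file** — one or more layers, each assigning every
  point a class c<sub>i</sub> ∈ {0, …, numClass − 1} (for example the
  gene-expression cluster a cell belongs to), in the same order and of
  the same length as the dataset's points. Layers may carry a name and
  per-class labels.

Both families are read and written in three dialects — JSON, XML and CSV
— with strict validation against a closed catalogue of issue codes
(shipped schemas live in `inst/schemas/`). JSON ↔ XML conversion is
lossless; CSV cannot express names, labels, the chain flag or a sparse
class numbering, and every such loss is reported as an explicit
`LOSSY_CSV` warning, never dropped silently.

A **scene** binds datasets and layers into up to four **worlds**
(side-by-side sub-views for comparison) with per-class visibility and
colour, and renders to either a single self-contained interactive HTML
document (drag to orbit, wheel to zoom; geometry embedded in a
machine-readable JSON data island) or a deterministic static PNG. Every
visible dataset always contributes a faint "shadow" of all its raw
points beneath the coloured classes, so hidden or unannotated points
keep their spatial context.

## Worked example

The package ships a minimal worked example: a 3-point dataset paired
with two information layers — one clustering that puts the first two
points together and the third alone, and one that separates all three.

```r
library(pointworlds)
ex <- worked_example()
cat(write_dataset(ex$dataset, "json")$text)
#> {
#>   "dataset": {
#>     "name": "minimal example",
#>     "chain": false,
#>     "points": [
#>       [0, 0, 0],
#>       [1, 0, 0],
#>       [0, 1, 0]
#>     ]
#>   }
#> }
validate_pair(ex$dataset, ex$information)   # zero rows: the pair is clean
```

Compile it into a one-world scene and look at what would be drawn:

```r
sc <- attach_dataset(add_world(scene()), 1, ex$dataset)
sc <- attach_layer(sc, 1, 1, ex$information)   # layer 1: "two clusters"
for (p in build_primitives(sc$worlds[[1]], sc$settings))
  cat(sprintf("%-9s %d points  class=%s  opacity=%.2f\n",
              p$kind, nrow(p$positions), p$tag$class, p$opacity))
#> particles 3 points  class=raw  opacity=0.15
#> particles 2 points  class=0  opacity=0.90
#> particles 1 points  class=1  opacity=0.90
```

The shadow batch holds all 3 raw points at low opacity; class 0 (the
pair) and class 1 (the singleton) sit on top in their palette colours.
`render_document(sc, "scene.html")` writes the interactive viewer;
`render_static(sc, "scene.png")` a publication snapshot.

The same objects are scriptable from a shell via the bundled CLI
(`inst/cli/pointworlds`): subcommands `validate`, `convert`, `render`,
`synth` and `stats`, exit code 0/1/2 for clean/validation-errors/usage.

```text
$ pointworlds stats cells.json clusters.json
dataset 'minimal example': 3 points, particles
bounding box: x [0, 1]  y [0, 1]  z [0, 0]
clusters.json layer 1 ('two clusters'): 2 classes, sizes 2, 1
clusters.json layer 2 ('all separate'): 3 classes, sizes 1, 1, 1
```

Importers bring common upstream data into the two-file model:
`table_to_dataset()` (PCA scores or any delimited coordinate table),
`labels_to_layer()` (cluster assignments, classes numbered by first
appearance) and `pdb_to_chain_dataset()` (chained Cα trace from PDB
text). `simulate_clusters()` generates Gaussian-mixture cell maps with
ground-truth layers, and `emit_fixture_suite()` writes a reference
corpus of clean and deliberately corrupted files with a manifest.

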