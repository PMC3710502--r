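---
title: "The pointworlds data model: files, scenes and rendering semantics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pointworlds data model: files, scenes and rendering semantics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pointworlds)
```

## The two-file model

pointworlds deliberately separates *where things are* from *what we know
about them*. A **dataset file** holds an ordered list of N points in
three dimensions and nothing else except a name and a `chain` flag; an
**information layer file** holds one or more per-point class
assignments over those N points. Points carry no identifiers: a layer
refers to a point purely by position, so both files must list entities
in the same order and the pairing is checked by length
(`validate_pair()`). This keeps each file trivial to produce from any
analysis environment — a matrix dump and a vector dump — at the cost of
making order sacred, which is why the readers guarantee order
preservation and the test fixtures use injective coordinates so any
reordering would be detected.

The `chain` flag switches between the two biological reading modes:
sequential data (a protein backbone, a trajectory) drawn as a polyline
through the points in file order, and population data (cells, PCA
scores) drawn as independent particles. A chained dataset of N points
has exactly N − 1 segments; a single chained point draws no line.

## Three dialects and what each can say

JSON is the primary dialect; XML carries exactly the same structure for
toolchains that emit it; CSV is a deliberately minimal on-ramp for data
that already lives in spreadsheets. The three readers accept the same
semantics wherever the syntax can express them, and the writers are
*canonical*: a given object always serialises to the same bytes, with
numbers printed in the shortest decimal form that round-trips to the
identical double. That makes write–read–write loops byte-stable, which
the test suite exploits heavily.

CSV is lossy by construction: it has no place for a dataset name, the
chain flag, layer names, class labels, or a class count larger than the
number of classes actually used. The policy is that *loss is always
explicit*: every field CSV cannot carry produces a `LOSSY_CSV` warning
at write time, and nothing else about the data is altered. One subtle
consequence: because a CSV information reader can only infer the class
count from the distinct values present, a layer whose classes are not
numbered contiguously (say values {0, 2} with 3 declared classes) would
not survive a CSV round trip. The writer therefore renumbers classes to
a contiguous 0-based range on CSV output — with a warning — so that
emitted text always re-parses; the partition itself is unchanged.

### Class identifier conventions

Files in the wild plausibly use either 0-based or 1-based class
numbering, and the format itself does not say which. The canonical
in-memory form is 0-based. A file whose values all lie in
[0, numClass − 1] is taken literally. A file whose distinct values are
*exactly* {1, …, numClass} cannot be a valid 0-based file (numClass
itself is out of range), so it is read as 1-based and shifted down,
with an `ONE_BASED_NORMALISED` warning attached to the parsed object. A
file valid under both readings (all values in [1, numClass − 1]) is
taken as 0-based — the reader never silently reinterprets data that
already parses. Everything else is a `VALUE_OUT_OF_RANGE` error, unless
the caller opts into repair mode, which raises `numClass` to cover the
observed maximum and says so. Strictness is the default because a
misread class assignment is a silently wrong figure.

### CSV family ambiguity

A dataset CSV is any file whose rows all have exactly three numeric
fields; an information CSV is anything else numeric. A three-column
all-integer CSV satisfies both readings — three coordinates, or three
layers of class values — and guessing would misclassify someone's data
eventually, so `detect_format()` refuses with `AMBIGUOUS_CSV_FAMILY`
until the caller states the family. The file-reading entry points
(`read_dataset()`, `read_information()`, and the CLI, where the family
is implied by argument position) only sniff the dialect, so the
ambiguity never bites when the caller already knows what the file is.

The CSV micro-dialect is fixed as: comma separator only, no header, no
quoting, "." as decimal separator, whitespace around fields trimmed,
LF or CRLF endings, blank trailing lines ignored.

## Scenes, worlds and display state

A scene holds at most four worlds — enough for side-by-side comparison
of layers or datasets without shrinking any view below usefulness — and
one *global* settings object (axis scales, raw/layer opacity and size,
centering), applied to all worlds alike. Per-world settings were
considered and rejected: the worlds exist to compare data under
identical viewing conditions, and independent scales would quietly
defeat that.

Attaching a layer to a bound dataset validates the pair and creates one
display state (visible flag + RGB colour) per declared class, coloured
from `default_palette()`: evenly spaced hues at saturation 0.65 and
value 0.9, which makes k = 2 complementary and keeps all pairs distinct
through k = 64. Customised states are remembered per (dataset, layer)
key, so toggling to another layer and back does not discard a user's
colour choices.

**Centering** subtracts each axis' bounding-box midpoint, not the
centroid. The midpoint gives symmetric display extents on every axis —
the visual intent of "centered around 0" — whereas the centroid of a
lopsided point cloud would leave the display visibly off-center. The
centroid alternative is noted here because the choice was genuinely
open; bounding-box centering also makes the operation idempotent, which
the tests assert. Scaling is applied after centering, per axis.

Defaults: raw (shadow) opacity 0.15, layer opacity 0.9, both sizes 1.0,
centering off (coordinates are displayed as inputted unless asked).
These are display conventions, not measurements; all are settable.

## Rendering semantics

`build_primitives()` compiles a world into a flat list of
renderer-agnostic drawables — particle batches and polylines with
colour, opacity and size — so that any backend can consume them. Two
invariants define the semantics and are enforced by tests:

- **Shadow completeness.** Every bound dataset contributes one
  low-opacity batch of *all* its points, before and beneath any class
  colouring. Hiding classes therefore never removes points from view;
  it only removes their colour. This keeps the spatial context (the
  outline of the whole tissue) visible while attention is on a subset.
- **Point conservation.** The visible class batches plus the hidden
  classes' point counts always sum to N per dataset, and a chained
  dataset contributes exactly N − 1 segments.

`render_document()` writes one self-contained HTML file: the geometry
as a JSON data island (`<script type="application/json"
id="pointworlds-data">`) and a small dependency-free canvas viewer
(orbit on drag, zoom on wheel). Nothing is fetched from the network, so
the file can be mailed or archived and still opens; tests verify the
absence of URL schemes and that the island parses back to exactly the
primitive set. World layout is full-width for one world, a split for
two, and a 2 × 2 grid for three or four. `render_static()` draws the
same primitives through an orthographic projection onto a PNG of the
requested size; the output is byte-deterministic for a given scene,
view and size.

## Importers

`table_to_dataset()` maps any delimited table through column selectors
(header names or positions) into a particle dataset, preserving row
order. `labels_to_layer()` converts a categorical vector into a layer
with classes numbered by *first appearance* — not lexicographically —
so class 0 is always the first cluster encountered, and the original
label strings become the class labels. `pdb_to_chain_dataset()`
extracts a Cα trace from PDB-format text (parsed with bio3d): `ATOM`
records named `CA`, first model, first alternate location per residue,
one selected chain, emitted as a chained dataset. Full-atom import is
out of scope — the backbone trace is what a point-and-line viewer can
meaningfully show.

## The synthetic cluster generator

`simulate_clusters()` draws an isotropic Gaussian mixture: k centers
(supplied, or uniform in the unit cube), each emitting `n_per_cluster`
points with coordinate-wise N(0, σ²) noise, paired with its
ground-truth layer. The defaults — k = 3 clusters of 100 points with
σ = 0.05 in a unit cube — give visually distinct but adjacent blobs, a
reasonable stand-in for a spatially clustered cell map at the scale the
viewer targets. The generator emulates exactly the *geometry* such data
presents (compact clusters in a bounded volume, cluster-major file
order); it does not emulate anisotropic or curved structures, spatially
varying density, annotation noise (points assigned to the wrong
cluster), or missing data. Tests passing on these fixtures therefore
demonstrate the plumbing — parsing, validation, conservation, rendering
— not robustness of any inference, of which the package performs none.

The generator is seed-deterministic bit-for-bit and restores the
caller's RNG state, so embedding it in other stochastic code cannot
perturb that code's stream. At σ = 0 every point equals its center
exactly; per-cluster sample means converge to the centers at the
standard σ/√n rate, which the suite checks across 50 seeds with a 4
standard-error band.

## Numerical and degenerate-input choices

- Numbers are written in the shortest decimal representation that
  round-trips to the same IEEE double (tried at increasing precision up
  to 17 significant digits), so canonical output is byte-stable across
  platforms.
- Duplicate points are legal — colocated biological replicates exist —
  but NaN and infinite coordinates are `BAD_COORDINATE` errors.
- A declared class with no member points is a warning
  (`EMPTY_CLASS`), not an error: declaring headroom is legitimate.
- An empty dataset (zero points) and an information file with zero
  layers are errors; a single point is fine (and a single chained point
  simply draws no line).
- XML booleans accept `true`/`false` case-insensitively; anything else
  is `BAD_BOOLEAN` rather than a guess.

## Problem sizes in the test suite

The property suites run 100 random files per family for the round-trip
and lossiness checks, 25 random scenes for conservation, an exhaustive
add/remove world state machine to depth 8, 50 seeds for the
mean-convergence check, and one 100,000-point document render as a
scale exercise. These sizes give the properties room to fail while the
full suite stays comfortably within a couple of minutes on one CPU.

## Known limitations

- No streaming parser: documents are read into memory whole, so the
  practical ceiling is what fits comfortably in RAM (hundreds of
  thousands of points is routine; hundreds of millions is not the
  target).
- The interactive document embeds its own minimal viewer; it offers
  orbit and zoom, not picking, animation or level-of-detail.
- CSV information files cannot represent sparse class numbering or
  declared-but-empty classes (see above); use JSON or XML where that
  matters.
- The PDB importer reads the Cα trace of one chain of one model only,
  and does not fetch structures remotely.
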