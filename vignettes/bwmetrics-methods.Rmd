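---
title: "Methods: from photograph to structural pattern metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from photograph to structural pattern metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bwmetrics)
```

`bwmetrics` describes spatial pattern in photographs of natural structures
— canopies, vertical vegetation profiles, bird-nest walls — by reducing
each image to a matrix over three states (black = 1, white = 0,
transparent = `NA`) and computing geometric summaries on that matrix. This
vignette documents the model, every tunable that matters, the numerical
conventions, and what the tests do and do not establish.

## Binarization

For each pixel the intensity of the red, green or blue channel, or their
average (`channel`, default `"rgb_average"`), normalized to [0, 1] by the
8-bit maximum, is compared with `threshold_value` (default 0.5, i.e. 50%
intensity). The comparison is strict: intensity < threshold → black;
a pixel exactly at the threshold is white. Grayscale images return their
single gray channel for every selector. There is deliberately no automatic
threshold selection (Otsu and relatives): images shot under difficult
light are better thresholded interactively in an external editor and then
read back in already-binary form, which the strict rule reproduces
exactly.

**Transparency.** Transparent cells model non-subject regions — for a nest
wall photographed over an erased background, everything that is not nest.
They take precedence over color classification and are excluded from every
numerator and denominator downstream. Two alpha polarities exist because
the method's published textual rule and standard PNG semantics conflict:
`alpha_rule = "above"` (default) marks a pixel transparent when its alpha
value exceeds the threshold, which is the rule as stated; `"below"` marks
it transparent when alpha is under the threshold, which is what a PNG
edited in GIMP or similar actually encodes (alpha = 1 opaque). Both are
first-class; analyses of editor-produced PNGs should use `"below"`. This
is the single most consequential switch in the package and cannot be
resolved internally — the two readings are mutually exclusive.

**Resampling.** Large photographs are usually reduced before analysis
(`compress_method`): `"proportional"` scales both dimensions by
`compress_rate` ∈ (0, 1]; `"width_fixed"`/`"height_fixed"` pin one
dimension and preserve the aspect ratio; `"frame_fixed"` pins both.
Scaled dimensions are rounded half away from zero with a floor of 1.
Thresholding happens at full resolution first and the binary matrix is
then downsampled by nearest neighbor (target cell ← source cell containing
the point `(i − 0.5) · src/dst`). This order keeps the domain strictly
binary and deterministic; an averaging kernel would have to be
re-thresholded and would entangle the two parameters. The choice is a
convention of this package — when comparing against numbers produced by
other software on the same photograph, small differences at high-contrast
edges are expected, which is why the reproduction checks on external
photographs carry tolerances while all synthetic checks are exact.

## Metrics on the binary matrix

Row 1 is the top image row; all heights count whole rows from the bottom
edge, so a metric reported in cm has granularity `height_size / n_rows`.

* **Denseness** — black fraction among non-transparent cells; openness is
  its complement. Sectioned variants tile the axis from the top (rows) or
  left (columns) with bands of `section_size`; the last, possibly short,
  band is kept; an all-transparent band reports `NA` rather than erroring,
  so batch output stays rectangular.
* **Height quantile** (`height_proportion`) — scanning rows bottom-up,
  the height of the top edge of the first row at which the cumulative
  black share reaches `proportion` (ties resolve to the lower height via
  the ≥ rule).
* **Holes** (`hole_runs_row`/`_column`) — maximal same-color runs within
  each line; a transparent cell terminates a run, because a hole cannot be
  asserted to continue across an unknown region. Section summaries use the
  sample standard deviation (n − 1); a single run reports `NA` sd.
* **Light gap** — per row, the cell counts from the left edge to the first
  black cell and from the last black cell to the right edge; a row without
  black reports the full width with a `no_black` flag.
* **Crest metrics** — a column's crest height is the row count from the
  bottom to the top edge of its topmost black cell; 0 for a column with no
  black (a gap drops the crest to the soil line, and such columns still
  participate in the topline). `topline` is the Euclidean length of the
  polyline through consecutive crest points at column centers, so a flat
  crest of `w` columns has length `w − 1` pixels; with physical scales it
  is reported in cm, and supplying only one of the two scales is an error
  rather than a silent pixel/cm mix.

## The aggregation index

The package's summary of clumping. For every interior cell (centers in
rows 2..n−1 and columns 2..n−1; neighbors may be marginal cells) that is
not transparent, the same-color-neighbor proportion (SCNP) is the number
of its 4 orthogonal neighbors with its color divided by its non-transparent
orthogonal neighbors; transparent centers are skipped. The observed mean
SCNP is standardized to

$$A = \frac{\overline{SCNP} - \overline{SCNP}_{min}}{\overline{SCNP}_{max} - \overline{SCNP}_{min}}$$

where the references are *constructed* arrangements with the observed
dimensions, black count and transparency pattern: minimum = fill the
chessboard parity classes (even row+column first, row-major, overflowing
into the odd class); maximum = row-major fill from the top-left. At half
density these are the exact chessboard (mean SCNP 0) and a side-split
(0.875 on a 6×6), giving A = 0 and A = 1.

Two conventions here are reverse-engineered rather than stated by the
published description, and are therefore pinned by tests instead of by
citation: (i) the neighborhood is the 4-cell von Neumann system — with 8
neighbors the 6×6 side-split gives 0.8125, not the published 0.875, which
rules it out; (ii) interior centers may use marginal neighbors — excluding
them also fails to reproduce 0.875. The extremal references are
constructive archetypes, not proven optima for arbitrary densities and
transparency patterns; on 4×4 grids at half density an exhaustive sweep of
all 12,870 arrangements confirms both constructions attain the true
extrema, and that check runs in the test suite. Degenerate inputs
(single-color images, or any case where the references coincide) report
`adjusted = NA` with a `degenerate` flag while still returning the
observed mean.

```{r}
aggregation_index(make_fixture("chessboard", 6, 6))$adjusted
aggregation_index(make_fixture("halves", 6, 6))$adjusted
```

## Circular remapping

`compress_to_circle` / `stretch_to_square` serve circular subjects
(hemispherical frames, dome nests). The published one-line description
fixes no geometry, so the mapping here is this package's own, stated for
reproducibility: angles about the grid center are preserved and each
radial ray is rescaled so the square boundary corresponds to the inscribed
disk boundary; sampling is nearest-neighbor at cell centers; the center of
an even-sized grid is the cell-corner point (n/2, n/2). Compression makes
exactly the outside-disk cells transparent; stretching fills corner
regions from boundary-radius values, walking marginally inward when
rounding lands on an outside-disk cell, so it introduces no transparency.
The maps are lossy near corners by construction; on a 101×101 half-split
the round trip recovers ≥ 95% of in-disk cells, and denseness of angularly
unbiased patterns is preserved to within 2% at 201×201 (both measured in
the test suite).

## Synthetic fixtures

`make_fixture` generates the archetypes every metric is tested on:
chessboard and side-split halves (the extremal aggregation panels),
i.i.d. random grids of given density, silhouettes (vegetation-profile
emulation: per-column crests from a seeded bounded random walk — first
crest uniform over the middle third of the height, steps uniform on
−2..2, clamped to [0, n_rows] — black below the crest), and a black disk
on transparent background (circular-subject emulation). The walk
parameters were chosen once to give crest variation at any size: steps of
±2 on profiles tens of rows tall produce realistic roughness without
sawtooth artifacts. Fixtures are bit-reproducible from (kind, dims, seed)
and the generator restores the caller's RNG state.

What the fixtures do **not** emulate: gradual illumination gradients,
JPEG chroma artifacts at vegetation edges, mixed pixels at silhouette
boundaries, lens distortion. Passing tests therefore establish the
correctness of the matrix computations and the I/O contracts, not the
field accuracy of a particular threshold on a particular camera; the
binarization threshold remains the user's scientific decision.

## Numerical conventions and test scale

All index arithmetic is exact rational-in-double (SCNP values are
multiples of 1/(4·interior size)); equality tests on synthetic inputs use
exact comparison, and only checks against externally produced photographs
or lossy codecs use tolerances. The oracle-equivalence sweep runs 10⁴
seeded random fixtures with dimensions up to 50×50 (one in five carrying
10% transparency) against naive cell-by-cell scanners for runs, crest
heights and SCNP; the exhaustive extremal check enumerates all C(16,8)
half-density 4×4 grids. These sizes keep the whole suite under two
minutes on one core while covering every code path; larger images add no
new arithmetic, only more cells.

## Known limitations

* The alpha-polarity ambiguity is exposed, not resolved; reading an
  editor-produced PNG with the default rule inverts the transparency mask.
* Extremal references are heuristics away from half density; the adjusted
  index can in principle fall marginally outside [0, 1] for unusual
  transparency patterns (never observed in 10⁴ random half-density grids).
* Holes are strictly per-row/per-column sequences; there is no 2-D
  connected-component analysis.
* No lens-projection correction (equidistant/equisolid) and no
  leaf-area-index inversion; the package reports proportions and
  geometry only.
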