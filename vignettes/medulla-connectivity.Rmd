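---
title: "Methods: column assignment, depth profiles and connectivity summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: column assignment, depth profiles and connectivity summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medcon)
```

This vignette documents the quantitative conventions the package implements,
the assumptions behind its synthetic data generator, and the numerical
decisions that were genuinely open.

## The analysis model

The package treats an EM reconstruction as three tables and a set of
skeletons: synapses (presynaptic cell, postsynaptic cell, 3-D location, one
record per postsynaptic partner at a T-bar), cell annotations (type, class,
identification status, photoreceptor subtype tags), and columns. All
coordinates are stored in nanometres — the native unit of whole-brain EM
skeletons — while every analysis parameter (kernel bandwidth, column pitch,
slab thickness) is specified in micrometres and converted once at the
module boundary.

**Depth axis.** Synapse depth is a signed percentage between the distal
(0%) and proximal (100%) neuropil surfaces; negative depths lie in the
optic chiasm, where photoreceptor axons receive and make a substantial
minority of their synapses. The depth axis is a contract: anything
providing the two surfaces and a linear projection qualifies. The built-in
backend is a planar slab (default thickness 40 µm), which is exact for the
synthetic generator and a deliberate desk-scale stand-in for the real
curved neuropil; mesh-based axes can be swapped in without touching any
downstream code, because every consumer works on depth fractions only.

**Layers.** Medulla layers M1–M10 are percent-depth bands with demarcations
0, 8.2, 26.2, 36.1, 45.9, 54.1, 62.3, 67.2, 76.2, 91.0, 100; the lobula
frame is 0, 4.2, 11.3, 22.4, 37.4, 49.4, 64.7, 100. Band membership is
half-open `[lower, upper)` with 100% belonging to the deepest layer — the
sources are silent on boundary membership, and the half-open rule is the
only choice that makes the bands a partition. Depths outside `[0, 100]`
report `"outside"`.

**Columns.** A column center is the unweighted center of mass of the
layer-M5 nodes of one Mi1 anchor cell. Points are assigned to the nearest
center, with distances measured in the total-least-squares plane of all
centers (the best planar approximation to the curved column sheet); exact
ties break to the smallest column id so that assignment is deterministic
and order-invariant. Pale columns are those claimed by at least one aMe12
vertical process; the detector accepts a column when the cell's nodes
there reach into the M6 band and ascend at least into the M3 band, which
admits both the short (M6→M3) and long (M6→M1) process variants. No
distance cutoff is applied — vertical processes sit inside columns by
construction, and the sources specify none. DRA columns are those whose R7
and R8 terminals both fall in the M6 band; a DRA flag overrides a pale
claim (empirically aMe12 enters the DRA only exceptionally), and every
column ends with exactly one of pale/yellow/DRA.

**Profiles.** One-dimensional synapse distributions (depth, planar radius
from a home column, dorsal-rim arc length) are smoothed with a zero-phase
Gaussian kernel by direct summation on a regular grid padded ±4σ beyond
the data, reported in synapses/µm. Conventional bandwidths: σ = 0.4 µm for
depth, σ = 0.6 µm for the planar and arc-length profiles. The grid step
(default 0.05 µm, an order of magnitude below either bandwidth) makes
discretization error negligible; direct summation was chosen over FFT
convolution because exactness at these problem sizes costs nothing.
Trapezoidal mass equals the synapse count to well within 1% (the ±4σ tails
carry < 0.01%).

**Dorsal-rim linearization.** The DRA column centers are fitted with a
direct least-squares conic constrained to an ellipse (the numerically
stable partitioned formulation), after centering and scaling for
conditioning; "least squares" alone underdetermines the method, and the
algebraic fit was chosen because it is deterministic, closed-form and
standard, with an optional geometric (orthogonal-distance) refinement.
Each synapse is then projected perpendicularly onto the ellipse: the foot
point minimizes distance over the parametric angle (720-point bracketing
scan plus 1-D refinement), arc length is measured from the positive
major-axis vertex in the direction of increasing parametric angle (any
fixed convention works; this one is stated for reproducibility) by
adaptive quadrature, and the normal distance is signed positive outside.
A point at the ellipse center has no well-defined projection and is an
error. A foot point within 1e-6 rad below the reference vertex is snapped
to angle zero rather than reported as a full perimeter.

**Summary tables.** Edge counts aggregate synapses per ordered (pre, post)
pair relative to a seed photoreceptor set, in either direction. A partner
cell is *reliable* with ≥ 3 seed synapses (the "> 2 synapses" convention).
Per type: `No.` reliable cells, per-subtype counts, their `Sum`, and
percentages `%R7`, `%R8` (source axis), `%p`, `%y` (mosaic axis, central
tables only — every DRA column expresses the same UV opsin, so the DRA
tables have no mosaic axis), `%Total` (share of the grand total including
pooled rows), and `%Total_R7`/`%Total_R8` (share of all seed R7/R8
synapses, again including pooled rows — the published totals include
them). Sub-threshold identified cells pool into `Identified_<3`,
unidentified cells into `Unidentified_>=3`/`Unidentified_<3`; cells
identified only to class are tabulated under the class label. A type is
called selective when ≥ 65% (inclusive) of its input comes from one source
class, evaluated on unrounded shares; whether the historical rule used
rounded or unrounded percentages is unstated, and unrounded is the choice
that does not depend on the presentation precision.

**Rounding.** All arithmetic is done at full precision; percentages are
rounded only at presentation, to one decimal, using round-half-to-even.
The tie cells of the reference tables (39/48 → 81.2, 27/48 → 56.2,
78/96 → 81.2) identify the rule unambiguously. One published cell
(95/837 = 11.35006%, printed 11.3) can only be obtained by rounding twice
(→ 11.35 → 11.3); the package reports 11.4 and the tests document the
single-cell exemption.

## What the synthetic generator emulates

`simulate_medulla()` draws, from one seeded stream:

- a hexagonal column lattice (default 30 × 26 ≈ 780 columns, 5 µm pitch —
  consistent with a rim stretch of ~10–17 columns covering ~50 µm);
- a contiguous run of 42 dorsal-rim columns along the lattice boundary;
- an independent pale/yellow mosaic on the remaining columns
  (pale probability 0.38);
- per column, two unbranched photoreceptor axons entering in the chiasm
  (negative depth) and terminating uniformly within their target band —
  central R7 in M6, central R8 in M3, both DRA types in M6 with R8-DRA
  strictly shallower;
- target cells from templates (arbor span in column units, layer profile,
  R7/R8 and pale/yellow weights, home-column boost, chiasm fraction),
  including a per-column Mi1-like anchor, an aMe12-like cell family whose
  vertical processes occupy exactly the pale set, Dm8-like home-boosted
  R7-exclusive cells, and DRA-exclusive rim cells;
- synapse counts per (column, overlapping target cell) drawn
  Poisson(mean × source weight × mosaic weight × home boost), placed at
  the source column with planar jitter below 0.3 pitch — so the nearest
  center is the true column by construction — at a depth drawn from the
  target's layer profile, or in the chiasm with the template's chiasm
  fraction (0.8 for the R7→R8 axo-axonal connection, mirroring the ~80%
  of that input found outside the medulla).

Default connectivity rates reproduce the *relative* selectivity structure
of the empirical tables (R7:R8 ratios, pale:yellow bias, DRA exclusivity)
at modest absolute counts; absolute-count behaviour of the summary
statistics is exercised separately through the packaged published-count
fixtures. Poisson counts are the simplest generative null — the sources
give no count distribution — and overdispersed alternatives would enter as
a config extension, not a change to any consumer.

What the generator deliberately does not emulate: realistic neurite
geometry (cells are node clouds and vertical chains, not biological
arbors), the curvature of the medulla sheet (the rim is straight in the
lattice; true elliptical rims appear in the geometry tests, where columns
are sampled from an actual ellipse), reconstruction errors, and partner
cells outside the photoreceptor pathway. Passing ground-truth recovery
tests therefore demonstrates correctness of the analysis operations under
the stated geometry, not robustness to tracing noise in real volumes.

## Numerical and testing choices

Degenerate inputs are rejected loudly: skeletons must be single-rooted
trees (cycles, dangling parents and duplicate ids are reported with line
numbers), ellipse fits need ≥ 6 non-collinear points and a conic that is
actually an ellipse, profiles need σ > 0, empty seed sets and empty column
lists are errors, and compartment breakdowns refuse synapse tables with
unset compartments rather than guessing.

Problem sizes in the test suite are chosen for coverage per second: the
shared synthetic medulla is 8 × 9 columns with a 9-column rim (~3.6k
synapses), the mosaic-interval check runs the full 780-column lattice once
(lattice generation only), the projection oracle uses a 10⁵-point two-stage
dense sampling of the ellipse against 60 random point/ellipse pairs in the
unit tests and 1000 in the acceptance suite, and the dorsal-rim profile
property compares the realized profile to the analytic expected density of
its own construction (peak location within two column pitches, 90% mass
width within 20%) — the localization statement is qualitative by nature,
since with ~4 µm column spacing and a 0.6 µm kernel the realized argmax
can hop one column under Poisson noise.

## Known limitations

- The planar-slab depth axis ignores neuropil curvature; per-column axes
  from mesh normals are out of scope, and the abstraction boundary exists
  precisely so they can be added.
- The visual identification of additional DRA columns "by inspection" in
  the original workflow has no algorithmic counterpart; the detector here
  requires both terminals measured, and flags columns with missing
  terminals indeterminate instead of guessing.
- Multi-cell pale claims are resolved by set union; deduplication beyond
  that (shared columns between aMe12 cells) is not attempted.
- The generator's absolute synapse counts are not calibrated to the
  published per-column totals, only the selectivity structure is.
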