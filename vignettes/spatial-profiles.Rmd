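---
title: "From serial cryosections to spatial protein profiles and distance-delay networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From serial cryosections to spatial protein profiles and distance-delay networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicewise)
```

## The problem

Serial cryosectioning turns a piece of tissue — here the mouse soleus
muscle, cut longitudinally from the muscle belly toward the tendon — into
an ordered series of thin (typically 20 µm) sections, each analyzed by
DIA LC-MS/MS. The result is a wide protein-group intensity matrix whose
columns are positions along a spatial axis. Two features make this data
awkward for standard label-free workflows:

* **per-slice input varies several-fold by construction**: the section
  area shrinks from ~1.7 mm² in the belly to under ~0.2 mm² at the
  tendon, so total protein input falls along the axis and ordinary LFQ
  normalization (which assumes comparable samples) breaks down;
* **missingness is heavy and structured**: dropout is intensity
  dependent (MNAR) on top of random losses (lost sections, LC-MS
  failures), and it concentrates in exactly the regions of biological
  interest (the muscle–tendon transition, where composition changes).

`slicewise` implements the downstream computational pipeline: floor
filtering, robust generalized-log normalization with per-slice input
correction, sliding-window completeness filtering, distance-based
imputation, trend-based marker selection, replicate axis alignment, and
a directed distance-delay network over the final profiles.

## Preprocessing model

Raw intensities below a floor (default `1e4`) are censored to missing:
values that low are dominated by noise and their presence/absence is
itself intensity driven. Censoring is strict (`x < floor`) and
idempotent.

Normalization is a per-sample scale calibration followed by a
generalized log. For sample $j$ a positive factor $s_j$ is estimated by
a least-trimmed-squares style iteration on the log2 ratios to a
geometric-mean reference profile, keeping the 90 % of proteins closest
to the current estimate (`trim_fraction = 0.1`); this assumes most
proteins are non-differential between neighboring sections. Calibrated
intensities are transformed with

$$h(z) = \log_2\!\frac{z + \sqrt{z^2 + c^2}}{2},$$

which is the arsinh-type variance-stabilizing transform: linear near
zero, and converging to $\log_2 z$ for $z \gg c$. The softening constant
$c$ defaults to the detection floor (`1e4`), the scale at which the
variance of the raw intensities stops being dominated by additive noise.
No additive offset is estimated in the calibration: protein-group
intensities from DIA post-processing carry no additive background, and a
free offset is unidentifiable on heavy-tailed abundances at realistic
protein counts (in trial fits it absorbed millions of intensity units
and corrupted the scale factors). A `log2-median` fallback is available
via `normalize_quant(method = )`.

Input correction then subtracts $\log_2(\text{total intensity}_j)$ per
sample, with totals computed from the raw floored matrix (missing
treated as 0). Two properties are worth keeping straight, and the test
suite asserts both:

* on the plain log2 scale, input correction cancels a per-slice scaling
  *exactly* — this is the sense in which profiles become "relative to
  per-slice protein input";
* the scale calibration *also* absorbs per-slice scalings (up to a small
  uniform drift, below 0.02 log2 units at intensities ≥ 1e5 in
  realistically sized matrices). Composing both, as the pipeline does,
  therefore re-expresses calibrated profiles relative to input rather
  than leaving them scale-free. The two corrections overlap by design;
  the second is what carries the biological meaning here.

## Sliding-window filtering and imputation

A forward-looking window of `after + 1` consecutive slices (default 11
slices ≈ 220 µm at 20 µm thickness) slides along each replicate. A
protein's per-replicate score is the *minimum* window missing-fraction —
it is enough to be locally dense somewhere — and a protein is kept when
the mean of these minima across replicates is ≤ 0.3 (inclusive), i.e. at
least one ~200 µm stretch with a 70 % data rate. Windows of 5–20
sections are reasonable; heavier heterogeneity wants wider windows.

Imputation is local and spatial. Per replicate and protein, each missing
slice looks at the window `[slice − 10, slice + 10]` on the *dense*
slice grid (physical gaps cost data). With strictly more than
`min_data_required` (default 3) observed points, an ordinary
least-squares line in slice predicts the value; predictions below the
minimum value ever observed in that replicate block are rejected — a
local line may not invent abundances lower than anything measured.
Raising `min_data_required` to 5 makes fits sturdier at the cost of
coverage. Cells that no window can serve are left to a per-sample
downshifted-normal pass (mean and sd of the sample's values below its
5 % quantile), the standard model for left-censored proteomics missing
values. Observed values are never modified, and all draws are seeded.

## Trend statistic and marker selection

To align replicates we need proteins whose abundance *trends* strongly
and consistently along the axis. Within a replicate, protein $i$ gets
the regression form of the SAM quantitative statistic:
$d_i = r_i / (se_i + s_0)$, where $r_i$ is the least-squares slope of
abundance on slice, $se_i$ its standard error, and $s_0$ an
exchangeability (fudge) factor shared by the replicate. $s_0$ is chosen
by scanning the 0, 5, …, 100 percentiles of the $se$ distribution and
minimizing the coefficient of variation of the within-bin median
absolute deviations of $d$ (100 quantile bins of $se$); this keeps
$|d|$ comparable across the variance range and guards zero-residual
rows. A permutation null (seeded) accompanies the scores; a plain
t-of-slope alternative is available (`trend.method = "tslope"`).

Across replicates, `mean` (of $d$), `absdiff` (the absolute summed
successive differences, which telescopes to $|d_{last} - d_{first}|$)
and `fscore = mean/absdiff` rank consistent strong trends; the marker
set is $|mean| > 5$ (strict). Note that $d$ scales with
$\sqrt{\sum_j (y_j - \bar y)^2}$: the threshold of 5 presumes
study-scale series (~175 sections). The desk-scale runs in this
package's tests use 80 slices per replicate, where the same threshold
yields a handful of markers; at 40 slices it yields almost none. The
threshold is configuration (`marker.min_abs_mean`), not a constant of
nature.

## Replicate alignment

Each replicate's slice axis is mapped to relative positions
`perc ∈ [0, 1]`. Marker profiles are smoothed onto a 5000-point uniform
grid by loess (degree 2, tricube weights); positions outside the data
range stay missing (no extrapolation). For each replicate pair a lag
scan over negative lags up to half the grid correlates the trailing
points of one profile with the leading points of the other, in both
pairing directions; the best lag per direction, expressed as a fraction
of the axis, is that marker's shift estimate. Per (pair, direction) the
median over markers is taken; for pairs anchored at the reference
replicate the direction with the larger median shift wins, and the
other replicate's axis is moved by ∓shift ("lo" pulls back a replicate
whose features come later, "up" pushes forward one whose features come
early). Ties in the lag scan break toward the smallest lag — least
deformation. The result is stored as `perc2`; only reference-anchored
pairs are applied (shifts are not composed transitively).

Two practical caveats, both visible in synthetic data:

* the default span of 0.75 oversmooths sharp junction profiles on short
  series; recovery of planted shifts to within 0.01 needs the junction
  resolved (e.g. span 0.3 at 100 slices, which is what the recovery
  tests use). `align.span` exists precisely because profile smoothness
  varies;
* monotone ramp-like profiles are *shift degenerate* — a shifted ramp is
  the same ramp plus a constant, so every lag correlates equally well
  and such markers contribute noise to the median. Junction-crossing
  (sigmoidal) markers carry the alignment signal; with enough markers
  the median absorbs the rest.

Finally the matrix is finalized in two variants: per-protein z-scores
within each replicate (`full-z`), and additionally a per-protein
`[0, 1]` range mapping across all samples (`full-z-range`), columns
ordered by (replicate, `perc2`). Zero-variance proteins are dropped.

## Distance-delay network

For every protein pair of the finalized (ranged) matrix, one profile is
slid against the other: for each overlap $i$ from `delayt` to $n$, the
leading $i$ points of one are correlated (Spearman by default) with the
trailing $i$ points of the other, in both directions, giving a
correlation-vs-delay curve on $-D \dots D$ with $D = n -$ `delayt`. The
minimum overlap `delayt` (default 0.45 · n) exists because correlations
on shrinking overlaps drift toward ±1; raise it if delays look
implausibly large. The best delay (first maximum on ties, i.e. the most
negative) and its correlation summarize the pair. Note that rank
correlation needs rank-informative profiles: on noiseless monotone
segments every overlap is perfectly rank-correlated, which is another
face of the ramp degeneracy above; the Pearson switch
(`network.method`) is the right tool for smooth low-noise profiles.

Pairs with |delay| ≥ 20 grid units are discarded (strict), each
surviving pair contributes its reverse with negated delay, and edges
with delay ≥ 0 form the directed network: an edge A→B with delay $d$
says A's profile trails B's by $d$ columns. Delay-0 pairs appear in both
directions. A data-processing-inequality pass then removes any edge
x→y (delay $d$, correlation $c$) for which some intermediate $i$ — an
out-neighbor of x and in-neighbor of y in the *unpruned* graph — has
both leg delays strictly positive, leg-delay sum $< d(1 + 0.1)$, and
|mean leg correlation| ≥ |c| − 0.1: a two-step path that explains the
direct edge with no more total delay and comparable correlation. All
edges are judged against the original graph and removals applied once,
so the result is order independent. The pruned edge list exports as an
unquoted CSV (edge id, source, target, delay, corr, delay_inv =
1/(delay+1)) ready for Cytoscape's table import.

Delays are in columns of the finalized concatenated matrix — roughly
slices; with `slice_thickness_um` set, the export adds `delay_um`.
Because the default matrix concatenates replicates, delay curves cross
replicate boundaries; with aligned axes this is the reference analysis'
convention and is kept as the default.

## What the synthetic generator does and does not emulate

`simulate_sections()` draws per-protein archetypes — a sigmoid crossing
a junction (the muscle-tendon transition), a gaussian bump, a linear
ramp, or a flat profile — with log-normal base abundances spanning ~4
orders of magnitude, adds log-scale gaussian noise (default sd 0.25),
multiplies in a per-slice loading curve falling 8-fold along the axis
(the area decline toward the tendon), applies logistic intensity-driven
dropout centered near the detection floor plus uniform random masking,
and shifts each replicate's axis (defaults 0, +0.05, −0.08 — biological
stretch/offset between animals). Three replicates of 60 sections and
120 proteins are the desk-scale defaults; every cell is reproducible
from the truth record plus the seed.

It does **not** emulate: correlated noise between neighboring sections,
peptide-level effects (shared peptides, protein inference), batch/run
drift, or replicate-specific *nonlinear* axis warping. Passing tests on
this generator therefore show that the algorithms recover what they
model — linear shifts, smooth trends, intensity-driven dropout — not
that real tissue obeys those models.

## Numerical choices

* Problem sizes in tests and the acceptance script are desk scale
  (tens of proteins, 60–100 slices per replicate, 200 permutations,
  alignment grids of 1000–5000), chosen so the whole suite runs in
  minutes on one core while staying in the regime where each method is
  identifiable.
* Window occupancy uses a strict bound (`> min_data_required`); the
  selection threshold is inclusive (`≤ 0.3`); the marker cut and the
  delay limit are strict. Boundary tests pin each of these.
* The imputation rejection floor is the minimum of the whole replicate
  block (all proteins), not per protein — deliberately conservative and
  matching the reference analysis.
* Argmax ties: delay curves take the first (most negative) maximum;
  the alignment lag scan takes the smallest |lag|.
* One seeded RNG stream per stage, derived from the run seed, with a
  fixed cell-visitation order — runs are bit-reproducible and a
  stopped-and-resumed run equals an uninterrupted one.

## Limitations

The alignment applies a single global shift per replicate — no
stretching or nonlinear warping; replicates whose physical lengths
differ strongly are only partially corrected by the relative axis. The
DPI pruning is heuristic (one pass, fixed tolerance), and delays carry
no significance measure. The trend statistic assumes an approximately
linear component along the axis; profiles that rise and fall
symmetrically score near zero and are invisible to marker selection —
by design, since such profiles do not anchor an alignment.
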