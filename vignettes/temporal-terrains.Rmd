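---
title: "Temporal GeneTerrains: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal GeneTerrains: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of what it computes and why the
defaults and numerical choices are what they are. The worked example in
the README shows the surface; here we explain the model underneath.

## The model

A *GeneTerrain* is a scalar field over the unit square. Each gene `i`
has a fixed position `(x_i, y_i)` and contributes an isotropic Gaussian
bump with amplitude equal to its (signed) expression value:

$$S(x,y) = \sum_i e_i \exp\!\left(-\frac{(x-x_i)^2 + (y-y_i)^2}{2\sigma_i^2}\right).$$

Positive amplitudes (upregulation) raise the terrain, negative ones
(downregulation) sink it. Crucially, `S` is **linear in the expression
vector**: for a fixed layout and fixed `σ`,
`terrain(e2 − e1) = terrain(e2) − terrain(e1)` pixel for pixel. This is
the formal content of the "frozen layout" contract — because every time
point and condition shares one set of coordinates, any pixel difference
between two terrains is attributable to expression change alone, never
to layout jitter. The test suite asserts this identity to 1e-10, and
`interval_deltas()` relies on it.

Positions come from the protein–protein interaction network: genes that
interact should sit close together, so that co-regulated complexes and
pathway neighborhoods show up as coherent hills or valleys rather than
scattered speckles. We minimize a Kamada–Kawai-style energy

$$E = \sum_{i<j} \frac{k^2 (d_{ij} - l_{ij})^2}{l_{ij}} + \frac{k^2}{d_{ij}},
\qquad l_{ij} = k \sqrt{\frac{\text{area}}{|V|}}\; L_{ij},$$

with `d_ij` the Euclidean distance, `L_ij` the shortest-path hop count
and the `k²/d` term a pairwise repulsion that keeps non-interacting
genes from collapsing onto each other.

### Spring scope: all pairs versus edges

There are two defensible readings of the spring term: restrict it to
network edges, or apply it to every pair via the graph-theoretic ideal
distance. We implement the **all-pairs form as the default**
(`spring_scope = "all_pairs"`): it is what classic Kamada–Kawai layout
does, it uses the shortest-path structure the ideal-distance formula is
clearly built for, and it produces globally coherent embeddings of
multi-hop neighborhoods. The edge-restricted variant is available as
`spring_scope = "edges_only"` for comparison; the repulsive term covers
all pairs in either case.

## The temporal pipeline

For each condition: replicates are averaged per time point (median
available via `aggregate = "median"`), one terrain is rasterized per
time point on the frozen layout, and consecutive time points yield
delta terrains plus up/down gene sets. Gene sets are exported as GMT
for external enrichment tools — enrichment itself is deliberately out
of scope. `interpolate_frames()` linearly interpolates the *expression
vectors* (not the pixels) between time points. With fixed σ the two are
identical (linearity again); interpolating expression keeps the
adaptive-σ variant well-defined, where the field is *not* linear in
expression.

"Significantly up/downregulated" has no statistical test here: the
up/down sets are defined by a symmetric magnitude threshold on the
change of Z-scored, replicate-averaged expression (default 1.0, i.e.
one pooled standard deviation of that gene). A `top_k` mode is
available when a fixed-size set per interval is preferable. No p-values
are produced, and none are implied.

## Parameters that matter

| Parameter | Default | Units / scale | Why |
|---|---|---|---|
| `top_n` | 1000 | genes | high-variance genes carry the dynamic signal; 1000 keeps terrains readable |
| `threshold_r` | 0.5 | Pearson r | retain genes co-expressed with ≥1 other selected gene; signed, inclusive |
| `sigma` | 0.03 | unit-square coords | ~3% of the layout span: wide enough to merge complexes, narrow enough to separate modules |
| `grid` | 512 | pixels | one pixel ≈ 0.002 units, well below σ; smaller grids are used in tests |
| `delta_threshold` | 1.0 | Z-score units | one per-gene standard deviation of change |
| `vmin`, `vmax` | −10, +10 | field units | amplitudes sum over genes, so the field range exceeds per-gene z-ranges; values are clipped, not errored |
| `eta` | 0.01 | step size | starting learning rate; backtracking halves it per rejected step |
| `epsilon` | 1e-6 | energy units | stop when an accepted step decreases E by less |
| `sigma_min`, `sigma_max` | 0.5·σ, 2·σ | unit-square coords | adaptive range; largest change ⇒ sharpest bump |

### Order of operations: variance before Z-scoring

Per-gene Z-scoring sets every gene's variance to 1, so ranking by
variance *after* normalization would be meaningless. The pipeline
therefore ranks genes by **raw** variance, applies the correlation
filter (correlation is invariant to per-gene affine scaling, so the
order relative to Z-scoring does not matter for it), and Z-scores
afterwards to obtain terrain amplitudes. `select_top_variance()` warns
if handed an already-normalized matrix.

### Correlation filter semantics

The filter retains a gene when its maximum **signed** correlation with
any *other* listed gene is ≥ `threshold_r`. Signed, because the intent
is co-expression (anti-correlated partners are not "co-expressed");
"at least one other", because that is the natural reading under which a
top-variance list shrinks only slightly (dropping just the genes
correlated with nothing). Correlations pool all samples across all
conditions and time points; the filter is deliberately not
condition-specific. Constant genes have undefined correlation and are
dropped with a warning.

### Adaptive smoothing

The adaptive variant modulates σ per gene by its change magnitude
between the compared time points: with
`m_i = |Δe_i| / max_j |Δe_j|`,

$$\sigma_i = \sigma_{max} - m_i\,(\sigma_{max} - \sigma_{min}),$$

so the fastest-changing genes get the sharpest bumps and static genes
blur into background. The linear inverse-magnitude map is the simplest
monotone realization of that intent and is the implemented contract;
the range defaults to `[0.5σ, 2σ]` and is configurable. Adaptive σ
applies to delta fields only — absolute per-time-point fields keep the
fixed σ so they remain mutually comparable. If every delta is zero the
map is undefined and all genes fall back to `sigma_base` with a
warning.

## Numerical choices

- **Descent with backtracking.** Plain fixed-step gradient descent on
  this energy can overshoot and diverge (the repulsion is stiff at
  short range). Each iteration therefore halves the step until the
  candidate does not increase the energy; accepted iterates are
  monotonically non-increasing, which also makes the stopping rule
  (`ΔE < ε`) meaningful. If no decreasing step ≥ 1e-14 exists, we are
  at a numerical local minimum and stop with `converged = TRUE`.
- **Initialization.** Seeded uniform positions in the unit square
  (default seed 17). The global RNG state is saved and restored, so
  layout calls do not perturb user code. Same seed + same inputs gives
  bit-identical layouts; different seeds give layouts that agree in
  energy to a few percent but not in coordinates (the energy is
  invariant under rigid motions, so coordinates are only defined up to
  one).
- **Disconnected networks.** Hop counts are undefined across
  components. Default policy substitutes (largest finite diameter + 1)
  so far-apart placement is encouraged but finite;
  `largest_component_only` instead drops minor components with a
  warning.
- **Layout normalization** maps the bounding box into `[0.05, 0.95]²`
  with one similarity transform — aspect ratio and all distance ratios
  preserved, 5% margin so σ=0.03 bumps are not clipped at the border.
  This fixes the coordinate scale that σ refers to.
- **Rasterization.** Pixel centers at `(j − 0.5)/W`; the stored grid is
  y-up (row 1 = bottom), flipped only at PNG-write time. Summation is
  exact over all genes by default — no kernel truncation — so the
  linearity identities hold to near machine precision and oracle tests
  are meaningful; a 4σ per-axis cutoff (`truncate = TRUE`) is available
  and documented as approximate.
- **Ties and determinism.** Variance ranking breaks ties by gene
  identifier (C-locale radix order); colors round half to even;
  montage labels use a bundled 5×7 bitmap font rather than a system
  font, so every output PNG is byte-deterministic given its inputs.
- **Degenerate inputs** are errors or warnings, never silent: constant
  genes in Z-scoring (zeroed, warning), coincident layout points
  (error naming the pair), single-sample matrices, empty networks,
  all-zero deltas under adaptive σ.

## The synthetic generator, and what passing tests mean

`make_network()` draws a stochastic block model: dense within modules
(`p_within`, default 0.3), sparse across (`p_between`, default 0.02),
plus a deterministic bridge chain so the graph is connected. The
modular structure is the premise the layout is supposed to recover —
tests assert that mean intra-module layout distance is smaller than
inter-module distance.

`make_expression()` gives each module a mean trajectory — transient
spike (linear rise over 4 h to a peak at 12 h, decay over 12 h),
sustained shift (step at 6 h), delayed activation (step at 24 h), or
flat — scaled by `amplitude` (default 3 expression units) and a
per-gene loading drawn from U[0.5, 1.5], with Normal(0, 0.2) replicate
noise. These choices make the programmed 9→12 h spike delta at least
1.125 units for the weakest-loading gene, comfortably above the
default detection threshold of 1.0 but close enough that noise
matters; recovery tests (10 seeds, 200 genes) ask for ≥90% sensitivity
with <5% false flags on flat genes.

The generator emulates: modular PPI topology, condition-specific
temporal programs, replicate noise, co-expression within modules. It
does **not** emulate: microarray/RNA-seq count distributions, batch
effects, heteroscedastic noise, hub-dominated degree distributions, or
incomplete/incorrect interaction annotations. Passing tests therefore
demonstrate that the machinery is correct and that programmed signals
of realistic magnitude are recovered — not that any particular
biological dataset will yield clean terrains.

## Problem sizes in tests

The shipped suite runs on deliberately small instances: 12-node graphs
against a Floyd–Warshall oracle, 20-gene fields against a double-loop
oracle, 16–64 px grids, 200-gene recovery fixtures, 24-gene end-to-end
pipeline runs. These sizes exercise every code path; production use at
~1000 genes and 512 px differs only in constant factors (the layout
stage is O(n²) per iteration, the rasterizer O(genes × pixels) via
separable kernels).

## Known limitations

- The layout is only defined up to rigid motion, and different seeds
  produce different (equally valid) embeddings; published figures are
  reproducible as a class, not pixel-wise, unless the layout TSV is
  shared — which is why `write_layout()` stores full double precision
  and the pipeline persists and reuses one layout per project.
- Gradient descent finds local minima of a non-convex energy; for
  strongly symmetric graphs different seeds can settle in mirrored
  basins.
- Terrain amplitude at a pixel sums nearby genes, so a dense clump of
  weakly changing genes can rival one strongly changing gene; the
  adaptive-σ variant mitigates but does not remove this.
- Up/down gene sets are threshold calls on effect size, not hypothesis
  tests; use them as input to enrichment, not as significance claims.
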