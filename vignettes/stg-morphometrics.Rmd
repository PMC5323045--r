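---
title: "Morphometrics of unipolar neuron skeletons: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometrics of unipolar neuron skeletons: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stgmorph)
```

## The problem

Neurons of small invertebrate motor circuits — the crustacean
stomatogastric ganglion (STG) is the motivating system — are unipolar:
the soma sits at the ganglion's rim and connects through a single
primary neurite to an expansive arbor that ramifies through a shared
neuropil. Classical morphometrics built for somato-centric neurons
(concentric-sphere Sholl analysis, soma-centred density maps) are
misleading here, and the arbors themselves are large (tens of
millimetres of cable), tortuous, and variable from animal to animal even
within an identified cell type. This package implements a morphometric
battery adapted to that geometry, a bootstrap test of whether subtree
terminals tile the neuropil, and a generative null model (minimal
spanning trees under a wiring cost) against which real arbors can be
compared. A synthetic-skeleton generator with complete ground truth
makes every stage testable without any imaging data.

## Data model

A reconstruction is a rooted tree of 3D nodes in micrometres
(`NeuronGeometry`). The root is the soma. *Segments* are maximal
unbranched chains (topological events only at their ends); *branch
points* are non-soma nodes with two or more children; *terminating
tips* are leaves that are neither soma nor axon. Axons are terminal
filaments tagged explicitly: automatic detection only *reports*
candidates (terminal filaments unbranched for at least 20 µm), because
axon identity is ultimately a judgement made on the preparation, not the
skeleton. All lengths are µm throughout; no unit inference is attempted.
Zero-length edges (a tracing artifact) are merged on construction with a
warning; node ids are arbitrary labels, and every statistic is invariant
under re-indexing (this is tested).

SWC (7-column) and the skeleton subset of NEURON `hoc` (section
declarations, `pt3dadd`, `connect`) are read and written; `hoc`
diameters are halved to radii. Other hoc statements are ignored with a
warning since deposited skeletons contain none that affect geometry.
When an SWC file's structural root is not its type-1 node, the tree is
re-rooted at the type-1 node nearest the root — deposited files vary in
this convention.

## The morphometric battery

**Paths and tortuosity.** One record per terminating tip: path length is
the sum of consecutive inter-node distances; tortuosity is path length
divided by the straight-line soma-to-tip distance. 1.0 is a perfectly
straight path; a tip coinciding with the soma makes the ratio undefined
and is flagged and excluded from distributions.

**Branch angles.** At a branch point `P_mid`, with `P_1` the far
endpoint of the parent segment and `P_2` the distal endpoint of a
daughter segment, the interior angle at `P_mid` follows from the law of
cosines and the reported angle is `180 - theta`, referencing the
daughter against the hypothetical continuation of the parent: straight
continuation scores 0°, a perpendicular daughter 90°. At
multi-furcations each (parent, daughter) pair contributes one angle;
daughter–daughter angles are not reported because the convention
references a parent continuation. The stored tracer-defined endpoints
are used directly (no resampling at a fixed arc length); zero-length
segments are skipped.

**Symmetry index.** At each bifurcation, `S = min(d1, d2) / max(d1,
d2)` where `d1`, `d2` are the summed lengths of all downstream segments
of the two daughters. Multi-furcations are excluded from SI
distributions. `S` is scale-invariant by construction.

**Rall power.** The exponent `X` solving
`parent^X = sum(daughters^X)` for the radii at a branch point. `X = 3/2`
is Rall's impedance-matching optimum. The solver works on the interval
`[1e-3, 20]` with tolerance 1e-6: wide bounds are needed because real
branch points produce exponents clamped near either end (daughters that
out-size the parent at every exponent push the minimiser to the lower
bound). For numerical stability the residual is minimised on the log
scale, `|X log(parent) - log(sum(daughters^X))|`, which has the same
roots as the raw difference but does not span fifteen orders of
magnitude across the interval; without this, a brute-force grid scan of
the raw residual is dominated by the scale of `parent^X` rather than
proximity to a root. An endpoint sign change is refined with `uniroot`;
otherwise a 512-point scan locates either a hidden root pair or an
interior residual minimum, and only a minimiser genuinely at a bound is
flagged `clamped`. The solver is tested against an independent 1e-4
grid scan on 1000 random radius triples (agreement < 1e-3).

**Linearized Sholl.** Because the soma sits outside the arbor,
crossings are counted on *somatofugal path length* rather than
Euclidean radius: 100 (configurable) linearly spaced distances from
zero to the maximum soma-to-tip path length; the count at distance `D`
is the number of parent–child node pairs whose cumulative path-length
interval straddles `D`, with the half-open convention
`[d_parent, d_child)` so a pair sitting exactly on a sampled distance
counts once. The count just above zero equals the number of primary
filaments; beyond the longest path it is zero. Counts and distances are
also returned normalised to their per-neuron maxima for cross-neuron
display. The implementation is verified against a brute-force crossing
count on small trees.

**Spatial density.** A Gaussian kernel density estimate over node x–y
coordinates with Scott's rule (full data covariance scaled by
`n^(-1/(d+4))` squared — the same convention as the common scientific
KDE implementations), evaluated at the nodes and rescaled to a maximum
of exactly 1 within each neuron. It is implemented in-package because
no installed KDE exposes evaluate-at-points semantics with this exact
bandwidth rule; the implementation is ~30 lines and tested on analytic
orderings (a dense cluster outranks an outlier; interior densities of a
uniform grid have coefficient of variation below 0.1).

**Diameters and hair-like neurites** (radius-annotated inputs only).
Segments are classed primary (the main path), secondary, tertiary
(sequential branching off the main path) and terminating tips; each
contributes its mean diameter. Hair-like neurites are maximal thin runs
(diameter < 1 µm throughout) longer than 50 µm measured from their
attachment point on the thicker structure.

## Subtrees and the tiling bootstrap

The *main path* is the union of segment chains connecting the soma to
each tagged axon (multi-axon neurons have several main paths sharing
the proximal trunk). A *subtree* is the collection of branches hanging
off one segment that departs the main path and reaches at least one
terminating tip, so the subtree count equals the number of qualifying
secondary branches. Each subtree's tip cluster gets a centre of mass
(mean tip coordinates), a cluster radius (mean distance from centre to
tips), and an elliptical neuritic field: the covariance ellipsoid of the
tip cloud with semi-axes `2 * sqrt(eigenvalue)`. The scale factor 2
(roughly 95% coverage per 1D Gaussian axis) is a parameter — the
original fit criterion is not specified anywhere, so it is exposed with
this default. Clouds with fewer than four tips or rank-deficient
covariance fall back to a sphere at the cluster radius.

Field overlap is counted in the x–y projection (a bird's-eye view of
the neuropil): the 3D ellipsoid is projected by Schur complement on the
z block of its quadratic form, and two projected ellipses intersect if
either's 360-point sampled boundary enters the other or either centre
is contained (tolerance 1e-6 µm). Exact conic intersection is avoided
deliberately for robustness; at this sampling density the error is far
below any biological signal. The overlap statistic is the number of
intersecting unordered pairs; the per-subtree alternative (number of
subtrees intersecting at least one other) is attached as an attribute
since the element-versus-pair convention is genuinely ambiguous.

The bootstrap asks whether the observed arrangement is more compact
than chance: pooled tip coordinates are permuted across subtrees
(without replacement — a design-based scramble), preserving each
subtree's tip count and root; the mean cluster radius and the overlap
count are recomputed per iteration; and one-sided p-values use the
add-one permutation correction `p = (1 + #{scrambled <= observed}) /
(1 + n)`, which cannot return zero. The default 2000 iterations shrink
automatically to the number of distinct assignments when that is
smaller. Calibration is tested: on *scrambled twins* (synthetic neurons
whose tips were themselves randomly re-assigned) the rejection rate at
alpha = 0.05 stays near 5% over 400 replicates, and on tiled synthetic
neurons the test rejects at p < 0.01 with 2000 iterations.

## Minimal spanning trees under a wiring cost

Synthetic arbors are grown greedily from a root — the reference
neuron's first branch point, since soma position is arbitrary in this
system — toward carrier points sampled uniformly in an ellipsoid
covering 95% of the reference's nodes. At each step the unconnected
point `p` minimising over tree nodes `n`

```
cost = ||p - n||  +  bf * ( PL(n) + ||p - n|| )
```

is attached, where `PL(n)` is `n`'s path length to the root. The first
term is the new cable; the second is the resulting root path length of
`p` weighted by the balancing factor `bf`. This is the single most
consequential interpretation in the module: the cost rule is stated in
the source literature only as "wiring cost + bf × path length cost",
and this form makes both terms extensive in the newly added cable.
Attachment happens only at existing nodes (no mid-edge splitting);
ties break to the lowest carrier index. `bf = 0` reduces to pure
nearest-point cable minimisation; growth is verified step-for-step
against an exhaustive re-computation oracle on small carrier sets.

The carrier count is tuned by bracketing and bisection (30-step budget)
until the tree grown at `bf = 0` has a branch point count within 20% of
the reference neuron's, then frozen across the sweep
`bf in {0, 0.1, ..., 0.6}` with a single shared carrier sample, so
sweep members differ only in `bf`. Tuning at `bf = 0` and sharing
carriers across the sweep are both choices the original description
leaves open; they maximise comparability across `bf`. Comparison uses
50-bin histograms on the union range of each metric (branch order,
root-to-tip length, tortuosity), normalised to each dataset's own
maximum so trees with different path counts are comparable, with the
divergence score the sum of absolute bin differences; total wiring is
compared directly with a within-20% flag. Across the sweep, cable is
non-decreasing and mean root-to-tip path length non-increasing in `bf`
— the cable/path trade-off the balancing factor expresses — and in
tested examples no single `bf` minimises the divergence of all metrics
simultaneously.

## The synthetic generator

`generateNeuron()` builds: a soma at the origin; a straight-by-design
primary neurite along +x (80 µm of soma offset, then 200 µm through
the "neuropil"); subtree roots evenly spaced along it; per-subtree
field centres on an alternating tiled grid (spacing 60 µm) or at
random; tips scattered around each centre (SD 10 µm); arbors built by
recursive partitioning of each tip set with daughter counts drawn from
the furcation mix (90% bifurcations, 8% trifurcations, 2% higher);
and straight axon filaments of 60 µm (comfortably above the 20 µm
detection rule). Defaults were chosen once to match the observed
regime — soma-to-tip paths mostly 200–800 µm, pooled tortuosity means
in the 2–4 range, a bifurcation-dominated furcation mix, diameters
tapering 18 → 6 → 3 → 1.5 µm with optional log-normal noise whose
sigma maps to the observed within-class CVs of 0.6–1.4 — and are not
adjusted per analysis.

Tortuosity is produced by perpendicular Gaussian jitter of amplitude
`tortuosityFactor * stepLength` at the interior nodes of each leg;
junctions, field centres and tip positions are never moved, so the
designed layout and tiling are preserved exactly. The mapping from
factor to tortuosity is monotone (approximately
`sqrt(1 + 4 * factor^2)` per leg for small steps); the default factor
1 lands median tortuosity near the observed 2–3. With
`tortuosityFactor = 0` every *segment* is an exact straight polyline
(chord equals arc to 1e-12) and designed path lengths and wiring are
recovered to machine precision. Note that soma-to-tip *path* tortuosity
still exceeds 1 in that case: a unipolar tree whose tips are reached
through a shared straight primary plus lateral subtrees necessarily
bends at junctions, and making every soma-to-tip path simultaneously
collinear would collapse the layout to a degenerate line. The ground
truth therefore records designed (piecewise-chord) path lengths rather
than asserting unit tortuosity.

What the generator does *not* emulate: anastomoses and tracing loops,
hand-like thick sub-structures, soma outlines, multi-scale node spacing
from mixed tracing software, and realistic axon trajectories beyond the
20 µm rule. Passing tests on synthetic data therefore demonstrate
correctness of the measurement machinery under known ground truth, not
fidelity of any particular biological claim about real reconstructions.

## Statistics and the pipeline

`groupCompare()` follows the original reporting convention: one-way
ANOVA when Levene's test (alpha = 0.05) does not reject variance
homogeneity, Kruskal–Wallis otherwise, and Tukey HSD letters in all
cases. The homoscedasticity procedure is not named in the source
description, so Levene was chosen and is recorded alongside a residual
Shapiro check in every result. These are deliberately thin wrappers
over `stats::aov`, `stats::kruskal.test`, `car::leveneTest` and
`multcomp::cld` — no novel statistics live here. `runAnalysis()` runs
directories of SWC/hoc files end to end, skipping files that fail
validation while logging them, and emits summary and long-format CSVs
plus a provenance record (versions, seeds, config, per-file log).
Re-running a config reproduces outputs byte-for-byte.

## Problem sizes in the test-suite

The suite regenerates every fixture from code: default synthetic
neurons of roughly 200 nodes; calibration over 400 scrambled twins with
199 radius-only scrambles each; power checks at the full 2000
iterations; Rall solver agreement on 1000 random triples; MST oracle
equivalence on 100 random carrier sets of up to 7 points. These sizes
were chosen as the smallest that exercise each claim at its stated
tolerance.

## Known limitations

- hoc support covers the skeleton dialect only; templates, mechanisms
  and stylised soma outlines are ignored (with a warning), and
  multi-point soma outlines collapse to a single root node.
- Rall powers from skeleton radii use the branch-point node and the
  first daughter nodes; radii measured from images, as in the original
  study, are out of scope.
- The ellipse-overlap test is a sampled approximation (360 boundary
  points); pathological near-tangencies below the sampling resolution
  can be missed.
- The MST cost rule is one reading of "wiring cost + bf × path length
  cost"; absolute cable values are not comparable to results obtained
  with mid-edge attachment policies, although the qualitative bf
  trade-off is.
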