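---
title: "Mapping cell-state plasticity onto spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cell-state plasticity onto spatial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastispot)
library(dplyr)
```

## The problem

During embryonic heart morphogenesis, cell populations move through
immature-to-mature state transitions whose timing and location are shaped by
blood flow. Single-cell RNA velocity describes these transitions per cell,
but the cells have lost their positions; bead-array spatial transcriptomics
(Slide-seq-style platforms) keeps positions but mixes transcripts from
whichever cell sat on each ~10 µm bead. `plastispot` bridges the two: it
condenses a velocity analysis into a per-cell-type *plasticity score* and
projects that score onto deconvolved spatial spots, then provides the two
spatial statistics used to read the resulting maps — a transmural
*layer position* profile for ventricular walls and a sub-domain
neighborhood analysis for valve regions.

## The plasticity score

Three ingredients, all scaled to $[0,1]$ by min–max scaling:

1. **Velocity magnitude.** For each cell $c$, $\|v_c\|_2$ — the L2 norm of
   its velocity vector projected into the 2-D embedding. Fast-moving cells
   are in dynamic transcriptional states. We deliberately require 2-D input:
   the score is defined on the visualization embedding, and silently
   accepting a high-dimensional velocity field would change its meaning.
2. **Net flow.** From the directed cell×cell transition-probability matrix,
   a cell's outflow mean is the mean of the *nonzero* entries in its row and
   its inflow mean the mean of the nonzero entries in its column (excluding
   zeros avoids bias from unconnected cells). The net flow is
   $\text{out}_c - \text{in}_c$: positive for sources feeding transitions,
   negative for sinks receiving them. Diagonal self-transitions carry no
   state-transition information and are ignored.
3. **Cell score and aggregation.** The cell-level plasticity score is the
   product of scaled magnitude and scaled net flow; the cell-type score is
   the mean over the type's cells, min–max scaled again across types, so the
   most plastic type scores exactly 1 and the most stable exactly 0.

Spatial projection multiplies the type score by the type's deconvolved
proportion in each spot,
$\text{score}_{C,s} = \text{score}_C \times p_{C,s}$, and per-spot maps sum
over a chosen type subset (e.g. fibroblast subtypes). The sum is *not*
renormalized over the subset: a spot only 40 % covered by fibroblasts can
contribute at most 0.4, which is the intended reading of a
proportion-weighted map.

### Numerical conventions

* **Degenerate min–max** (all values equal): every value maps to 0. A flat
  vector carries no ordering evidence, and "no variation" should read as
  "no plasticity signal", not as an arbitrary constant.
* **Empty nonzero sets** (a cell with no nonzero out- or in-edges): the
  corresponding mean is 0.
* **Negative transition entries are rejected**, not clipped. Some velocity
  tools emit signed correlation graphs; splitting or thresholding such a
  graph is an upstream modelling decision we refuse to make silently.
* Dominant-type ties (exactly equal proportions) break to the
  lexicographically smallest type name — deterministic and seed-free. With
  continuous deconvolution output ties have probability zero, so the rule is
  a documented convention, not an inference.

## Spot quality control and smoothing

Bead arrays accumulate low-count "smear" signal outside the tissue section.
The filter removes a spot iff it is **both** low-count
(`total_counts < 100`) **and** sparsely neighbored (≤ 15 neighbors within
100 µm). We considered the opposite polarity (retain only low-count dense
spots) and expose it as `polarity = "literal"`, but the default is the only
reading under which high-count tissue spots survive; smears are low-count
beads outside dense tissue. Neighbor counts exclude the spot itself and are
computed with grid bucketing, never a dense pairwise distance matrix.

Smoothing uses a truncated Gaussian kernel
($w_{sj} \propto e^{-d_{sj}^2 / 2\sigma^2}$, normalized), with defaults
$\sigma = 46.37$ µm, truncation at $3\sigma$ (beyond which the kernel mass
is negligible; the truncation radius is configurable), and a coverage
requirement of at least 10 spots (including the spot itself — a spot always
covers itself, whereas neighbor *counts* never include it; both conventions
are stated on the functions). Spots failing coverage are excluded from the
smoothed output rather than passed through unsmoothed, treating the
minimum-coverage parameter as a validity requirement. Counts are converted
to within-spot proportions before averaging so bead depth does not bleed
into neighbors; raw counts remain untouched for tools that need them.
Smoothing is a convex combination: values stay within the neighborhood's
range and nonnegative.

Single-cell QC removes cells on any of: doublet score > 0.25, detected
genes outside [300, 10 000], mitochondrial fraction > 10 %. Cells missing a
metric are flagged and removed, never silently kept.

## Layer-position analysis

Given manually annotated inner and outer boundary layers of a ventricular
wall, each spot's layer position is
$d_\text{outer} / (d_\text{outer} + d_\text{inner})$ with distances to the
nearest boundary spot: 0 on the outer (epicardial) edge, 1 on the inner
(endocardial) edge. The construction is invariant to rigid motions and
needs no registration. The same construction along upper/bottom boundaries
gives an axial coordinate used to segment the wall.

Profiles bin the layer position into 10 equal-width bins and the axial
position into 5 segments (half-open bins, last bin closed at 1; boundary
spots are regular members). Within each segment, a bin's type proportion is
the count fraction of spots whose *dominant* type is that type. The summary
profile is the **unweighted mean of per-segment fractions** (segments are
replicates of the transmural pattern, so pooling counts would overweight
thick segments), with a 95 % band from the 2.5th/97.5th percentiles across
segments. Percentiles use linear interpolation between order statistics
(R's type-7 default); bins empty in a segment are excluded from that bin's
mean and band rather than imputed as zero, since an empty bin observes
nothing. Both choices are config-free conventions stated here because no
single standard exists.

## Valve sub-domain analysis

Sub-domain labels are inputs (from any spatial-domain method); the package
implements what is done *with* them:

* **Cluster-number selection**: given an ARI stability value per candidate
  k, take the first run of ≥ 5 consecutive candidates (4 in the refinement
  round) with ARI > 0.65 and pick the k with maximal ARI inside the run,
  ties to the smallest k. The rule is agnostic to what the ARI compares;
  absence of a qualifying run is an explicit error, not a silent fallback.
* **Regional plasticity**: mean per-spot fibroblast-summed plasticity per
  sub-domain; rank 1 = most plastic; ties break by original label so
  ranking is reproducible.
* **Composition rule**: type fractions sorted descending; types below 5 %
  are ineligible; eligible types accumulate until the included mass first
  reaches 90 % (the crossing type included). Applying eligibility before
  accumulation is the default; the alternative order is selectable
  (`rule_order = "accumulate_first"`) and agrees with the default whenever
  no sub-5 % type precedes the crossing point.
* **Neighbor calls**: a type is a per-sample candidate if included in ≥ 2
  sub-domains, and a condition-level neighbor if a candidate on ≥ 2
  distinct days of that condition. We evaluate the sub-domain threshold per
  sample (not pooled across days) because the per-day compositions are the
  unit of observation.

A thin driver (`recursive_subdomains()`) wires a user-supplied clustering
callback into the two-round scheme — whole tissue first, then the domain
with the highest valve-cell proportion — without imposing any clustering
model.

## The synthetic generator

Real chick-heart arrays are large (8 000–68 000 spots per sample) and their
ground truth is unknowable; the generator builds small tissues whose truth
is planted, so every downstream module can be tested for *recovery*, not
just for running:

* **Geometry**: a half-annulus (ventricular wall cross-section: inner and
  outer edges, two cut ends) and a truncated wedge (valve leaflet: narrow
  free tip, wide base). Spots sit on a jittered 20 µm grid clipped to the
  footprint, echoing beads dispersed in a plane. Boundary rings are the
  spots within one grid spacing of the exact geometric boundary — the
  synthetic stand-in for a manually traced "single layer of spots".
* **Depth**: negative binomial around `mean_depth` (default 1000, dispersion
  2), reflecting the overdispersion of per-bead counts; platform depth
  distributions vary, so both parameters stay configurable.
* **Composition**: per-type weight profiles over the true radial fraction
  (logistic by default, emulating graded maturation across the wall), plus
  zero-truncated Gaussian abundance noise. Noise-free normalized weights
  are stored as ground-truth proportions.
* **Transition chain**: each non-terminal cell sends mass `forward_p` to
  random next-stage cells and optionally `noise_p` elsewhere; terminal
  cells have zero outflow. Velocities point at the next stage's centroid
  with magnitude $1 - \text{stage fraction}$. With noise off, stage-wise
  net flow and velocity magnitude are exactly constant within stages, so
  the planted source scores exactly 1 and the sink exactly 0 — an exact
  recovery target, not an approximate one.
* **Smears**: count Binomial(n spots, `smear_fraction`), uniform totals in
  [1, 50], scattered 5–15 grid spacings from the nearest tissue spot
  (annulus smears always beyond the outer radius). Smears are modelled as a
  sparse off-tissue field rather than a rim hugging the margin: a smear
  sitting within the 100 µm neighbor radius of dense tissue is, by the
  count-and-neighbor definition, not separable from tissue at all, and a
  field dense enough to self-neighbor above threshold stops being "smear"
  and becomes a second tissue. The placement encodes what the QC rule can
  meaningfully be asked to remove.

Everything is a pure function of parameters and seed; identical calls are
byte-identical.

### What the generator does not emulate

Gene-level biology is absent: the gene panel is an arbitrary fixed simplex,
so marker structure, spatially varying expression, and anything
deconvolution would actually estimate are out of scope — abundances are
*planted*, standing in for a deconvolution tool's output. Passing recovery
tests therefore demonstrates that the scoring, positioning and composition
machinery is correct, not that deconvolution or velocity inference would
succeed on real tissue. Segmentation errors, platform-specific spatial
artifacts (tears, folds), and day-to-day composition drift are likewise not
modelled.

## Problem sizes and verification

The test suite and the analysis script work at deliberately desk-friendly
sizes: a half-annulus of ~1 000 spots (r 300–600 µm, 20 µm pitch), a wedge
of ~400 spots, transition chains of 120–360 cells. These sizes keep every
property sharp (the layer-position rank correlation against true radius is
already ≥ 0.99 at this density) while the whole suite runs in about a
minute and a half. Net-flow correctness is checked against a brute-force
double-loop reference: exhaustively over all 2- and 3-cell graphs with
entries on a {0, 0.25, 0.5, 0.75} grid and over a large fixed-seed sample
of 4-cell graphs, with exact equality required. Percentile bands are
checked against an independent order-statistic interpolation oracle, and
hand-worked examples (3-cell net flow, the composition walk, the ARI run
rule) are frozen into the tests.

## Known limitations

* The plasticity score inherits every bias of the upstream velocity model;
  the package treats the transition graph as ground truth.
* Min–max scaling makes scores *relative within a dataset*: a score of 1
  means "most plastic type here", and scores are not comparable across
  independently scaled datasets.
* Layer position assumes the annotated wall is a topological band between
  its two boundaries; it degrades on branching or strongly folded regions.
* The composition rule's 5 %/90 % thresholds are conventions; both are
  arguments, and sensitivity to them should be checked on real data.
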