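---
title: "Categorical morphospaces and disparity through time: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Categorical morphospaces and disparity through time: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floradisp)
```

## The problem

Floral organization (the Bauplan: numbers, arrangement and fusion of floral
organs) is naturally described by categorical characters — some unordered
(e.g. anther dehiscence type), some ordered (e.g. merism classes, ovary
position). Quantifying the morphological variety (*disparity*) of sets of
flowers, comparing it among clades and stratigraphic time bins, and placing
both observed species and reconstructed ancestors into a common
*morphospace*, requires a coherent chain of methods for categorical data
with substantial missing, inapplicable and polymorphic entries. This
package implements that chain end to end and ships a synthetic-data
generator so that every stage can be exercised and validated without any
external dataset.

## Data model

A `trait_matrix` stores one token per taxon x character cell: an integer
state code, a polymorphic set (`"0&2"`), `"?"` for missing, or `"-"` for
inapplicable. Missing and inapplicable cells are distinguished in the data
model and audits (inapplicability is structural: e.g. perianth phyllotaxis
does not exist in a flower without a perianth) but pooled whenever
distances are computed, since both mean "no comparison possible".
Applicability is encoded as explicit constraint rules — a trigger state
forces a list of dependent characters to be inapplicable — shipped as data
(`inst/extdata/floral_constraints.csv`), not code, so alternative rule
lists can be swapped in.

The bundled 30-character floral schema has 17 binary, 8 three-state, 3
four-state and 2 five-state characters covering the whole flower (1), the
perianth (8), the androecium (11), the gynoecium (8) and pollen (2).
Count-like characters (merism, whorl counts, stamen/carpel number classes,
ovary position) are ordered; types and attachments are unordered.

Polymorphic cells are resolved once per analysis run by drawing one of the
recorded states with equal probability (`resolve_polymorphism()`, seeded).
Resolving per run — rather than per metric — keeps all metrics of a run
internally consistent; rerunning with a different seed measures the
sensitivity of results to polymorphism resolution.

## Mean character difference

The distance between two taxa is the *mean character difference*: the
average over all characters observed in both taxa of a per-character
dissimilarity in [0, 1],

* unordered character: 0 if the states are equal, 1 otherwise;
* ordered character with *k* states: |code_i − code_j| / (k − 1).

This is the Gower-type treatment of mixed categorical data; the ordered
scaling uses the theoretical range (k − 1) so that every character can
contribute at most 1 regardless of which states happen to be observed (an
observed-range rescaling would make distances depend on the sample; the
theoretical range keeps them comparable across subsamples, which matters
for rarefaction).

A pair of taxa sharing no observed character has an undefined distance.
Complete matrices are obtained by a greedy rule: repeatedly remove the
taxon involved in the most undefined pairs (alphabetical tie-break) until
none remain; removals are logged. This is a minimal-loss completion; the
drop log makes the rule auditable. The mean character difference is not a
metric (the triangle inequality can fail when different pairs are compared
over different character subsets), which is one reason the ordination
below is nonmetric.

## Disparity metrics

Within a group with *n* taxa, the C(n, 2) within-group pairwise distances
yield:

* `meanD` — their mean (density of the group in morphospace), with `sdD`
  their standard deviation;
* `maxD` — their maximum (the group's range);
* rarefied distributions of either metric: subsample *m* taxa per group
  without replacement (default *m* = smallest group size − 1), **recompute
  the distance matrix on the subsample**, evaluate the metric; repeat
  (default 1000 replicates). Recomputing distances on the subsample, rather
  than subsetting the full matrix, also re-runs the undefined-pair
  completion at the subsample level;
* `Ddelta` — a group's contribution to total disparity, defined here as
  `Dtot − meanD(dataset without the group)`, so a positive value means the
  group's presence raises total disparity. A `sign` flag exposes the
  reverse convention, because the two conventions coexist in the
  literature and differ only by sign;
* eccentricity — a taxon's mean distance to all other taxa of a reference
  set (row means of the distance matrix); the highest-ranked taxa are the
  morphological outliers at the edge of the occupied morphospace.

Reported `sdD` is the standard deviation over the pairwise distances
themselves, not over rarefaction replicates.

For disparity through time, fossils are pooled into stratigraphic bins —
Early Cretaceous (145–100.5 Ma), Late Cretaceous (100.5–66 Ma), Paleogene
(66–23.03 Ma) — by the midpoint of their stratigraphic age range, with
living species forming a fourth pool. The midpoint rule is a choice (the
alternative — require the whole range inside one bin — discards every
range straddling a boundary); it is configurable, and Neogene fossils are
excluded by default because too few adequately described fossil flowers
exist in that interval to support group statistics.

## Theoretical morphospace

The unconstrained number of state combinations is the product of
per-character state counts — for the bundled schema 2^17 x 3^8 x 4^3 x 5^2
= 1 375 941 427 200 (~1.38e12). This is computed in exact integer
arithmetic (base-1e4 digit vectors) because the product exceeds the 2^53
integer range of doubles for only moderately larger schemas.

A background sample of theoretical combinations (default 2000) is drawn by
independent uniform per-character draws, with constraint rules applied
(triggered characters become inapplicable, treated as missing in
distances) and duplicate rows rejected. Uniformity is defined over raw
combinations *before* constraint masking; a rejection watchdog detects
requests exceeding a small constrained space. Theoretical rows enter the
ordination only — never the disparity metrics or group statistics, which
are strictly empirical.

## Ordination and diagnostics

The morphospace is visualized by nonmetric multidimensional scaling of the
distance matrix (k = 2), using Kruskal stress-1 with primary tie treatment
(vegan's `monoMDS` engine) from multiple random starts (default 20),
keeping the lowest-stress solution. Because only ranks of distances are
used, the configuration is defined up to rotation, reflection and scale;
the returned coordinates are therefore centered, rotated to principal
axes, and sign-fixed (the largest-coordinate point is positive on each
axis) so runs are comparable. Diagnostics: Kruskal stress-1; the Shepard
point set's nonmetric fit r² (1 − RSS of the isotonic regression of
configuration distances on observed dissimilarities / total SS) and linear
fit r² (squared Pearson correlation of the two). A 30-character categorical
space does not embed well in the plane: stress around 0.3 is expected and
the ordination is read as a map, not a measurement; all statistics run on
the distance matrix itself, not on the ordination coordinates.

Group centroids are per-axis means of member coordinates (computed on
empirical members only). Morphospace coverage of a subset is the area of
its 2-D convex hull divided by the hull area of a reference set (default:
all ordinated points including the theoretical background).

## Group statistics

* Kruskal–Wallis (with tie correction, `stats::kruskal.test`) compares the
  pooled within-group pairwise distances among groups. These pairwise
  values are not independent observations — each taxon participates in
  many pairs — so the test is reported as a descriptive device for
  distance distributions, which is how it is conventionally used with
  disparity boxplots; p-values should be read accordingly. Post hoc:
  Siegel–Castellan pairwise mean-rank comparisons at Bonferroni-adjusted
  critical differences, summarized as a compact letter display (greedy
  clique cover of the non-significant-pair graph, alphabetical
  tie-breaks).
* PERMANOVA (npMANOVA) operates directly on the distance matrix through
  the sums of squared distances; the permutation p-value is
  (#{F* ≥ F} + 1)/(n_perm + 1) with label permutations (default 9999,
  seeded). On univariate Euclidean data the pseudo-F reduces exactly to
  the classical one-way ANOVA F, which the tests exploit as an algebraic
  oracle; `vegan::adonis2` serves as an independent cross-check. Pairwise
  PERMANOVAs use a Bonferroni multiplier equal to the number of pairs.
* Pearson correlation tests (`stats::cor.test`) relate group-level
  summaries (e.g. meanD vs Ddelta, meanD vs species richness or clade
  age).

## Ancestral state reconstruction

Each character is reconstructed independently on a dated tree under the
Mk model (continuous-time Markov chain with k states): ER (one rate) and
ARD (k(k−1) rates) are fitted by maximum likelihood (Felsenstein pruning;
L-BFGS-B on log rates, multiple starts for ER, the ARD search warm-started
from the ER estimate) and compared by AIC. The root prior is uniform
(1/k), configurable to the stationary distribution. Tips whose cell is
missing, inapplicable or polymorphic are dropped before fitting
(`ape::drop.tip` handles the branch-length bookkeeping).

Ancestral state probabilities at internal nodes come from two routes:
analytic marginals (two-pass algorithm) and stochastic sampling of joint
node configurations, drawn exactly backward from the root's conditional
distribution (default 500 draws, seeded). The node draws are exact
conditional samples, so full branch histories are not simulated: given the
states at both ends of a branch, the interior of its history cannot change
any node-state frequency, and node-state frequencies are the only
quantity consumed downstream. Sampled frequencies converge to the
marginals as the number of draws grows, which the tests verify.

The most probable state per character and node is assembled into an
ancestor row; ties and nodes lost in per-character pruning become missing
cells (and are logged). Ancestor rows are appended to the matrix before
distances so reconstructed ancestors can be placed in the same
morphospace. Note that a combination of per-character argmax states need
not satisfy the applicability constraints jointly and need not be a
combination displayed by any living species; it is a summary of per-node
marginal tendencies, which is the standard caveat of this placement
approach.

## Synthetic data: what it emulates, and what it does not

`generate_matrix()` draws, for each character, a shared Dirichlet base
profile of state frequencies; each group's sampling distribution mixes
this base with a point mass on a group-specific preferred state, the
mixing weight being the `divergence` knob. At divergence 0 all groups draw
from the identical distribution (exchangeable; between-group and
within-group distances coincide in expectation); at divergence near 1
groups are nearly fixed for different states. Constraint rules are applied
to the drawn states first; missing cells are then overlaid so that
`missing_rate` is the expected *total* missing + inapplicable proportion,
and polymorphic cells (a second distinct state) are overlaid on the
surviving observed cells at a rate adjusted to yield the configured share
of all cells. Defaults follow the composition of the floral dataset this
pipeline targets: ~32% missing+inapplicable for living species, ~36% for
fossils, ~3%/~2% polymorphic, fossil age midpoints spanning 145–2.6 Ma
with log-uniform range widths of 1–20 Myr (stratigraphic uncertainty
without modelling geology), 1201 living species in 11 groups plus 121
fossils in the study-scale wrapper `generate_study_dataset()`.

`generate_tree_with_characters()` simulates a birth–death tree rescaled to
a stated root age (default 140 Myr) and evolves each character under a
known ER process, recording true internal-node states for recovery
scoring.

What the generator does **not** emulate: real angiosperm character
correlations beyond the applicability rules, phylogenetic signal in the
matrix generator (groups are exchangeable draws, not clades), uneven
preservation of fossil characters by organ, or the actual state-frequency
profiles of the floral dataset. Passing tests therefore demonstrate that
the machinery is correct and well-calibrated under controlled conditions,
not that any particular empirical result is reproduced; empirical
reanalysis requires the real matrix as input.

## Numerical choices

* Distances in double precision end to end; no rounding before statistics.
* nMDS: stress-1, primary ties, convergence at stress < 1e-6 or scale-factor
  criteria, max 300 iterations per start, 20 starts by default.
* Mk: rates bounded in [1e-9, 1e4] on the log scale; matrix exponentials
  via eigendecomposition (`ape::matexpo`) with negative round-off clipped;
  constant characters short-circuit to the rate floor with a degenerate
  flag.
* Permutation p-values never report 0: (count + 1)/(n + 1).
* Exact integer combination counts via base-1e4 digit arithmetic.
* Greedy undefined-pair removal breaks ties alphabetically, so results are
  independent of input row order.

## Problem sizes used in the shipped checks

The package's own test suite and the acceptance script run on synthetic
data sized to exercise the full pipeline while staying light: study-scale
matrices (1322 taxa x 30 characters) for audits, distances, disparity
through time and group statistics; a stratified subsample (~400 living +
fossils + 500 theoretical rows) for the ordination; 199 label permutations
for PERMANOVA in the scripted run; oracle comparisons on 5–20 taxa where
exhaustive enumeration is feasible; ER recovery at up to 500 tips. All
sizes are set in code and can be raised by the user.

## Known limitations

* The Kruskal–Wallis input (pairwise distances) violates independence; see
  above.
* Disparity is not phylogenetically corrected; variance-based disparity
  metrics (sum of ranges, product of variances) are out of scope.
* No hidden-rate Mk extensions; no fossil-tip ASR.
* nMDS stress values are engine- and start-dependent diagnostics;
  identical data can yield slightly different stress across engines.
* The greedy completion rule for undefined pairs is one defensible choice
  among several; the drop log records exactly what it did.
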