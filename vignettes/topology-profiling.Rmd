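---
title: "Topology-based expression profiling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-based expression profiling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topoprofile)
library(dplyr)
```

## The problem

Tumor cohorts profiled on expression microarrays are heterogeneous: a
malignancy such as glioblastoma comprises molecular subtypes whose samples
form "pockets" of high density in expression space. Standard clustering
struggles here for two reasons. First, with ~10^4 genes and ~10^2 samples,
most genes are irrelevant to the subtype contrast and drown the signal, so
the gene panel must be chosen *before* clustering — yet at that point the
group memberships needed by supervised screens are unknown. Second, there is
no natural metric on expression space, so methods that depend on spectral
quantities computed from a somewhat arbitrary distance tend to be fragile.

`topoprofile` addresses both with a two-stage, purely topological pipeline:

1. **Gene selection.** A scale-invariant width statistic flags genes whose
   expression across all samples is *bimodal* (a necessary condition for a
   gene to separate two subtypes), and zero-dimensional persistent homology
   over gene–gene correlation distances groups the survivors into coherent
   co-expression modules, from which two gene panels are drawn.
2. **Sample partitioning.** The same persistence machinery, applied to
   sample–sample correlation distances over the panel genes, bisects the
   cohort; each group is trimmed to a tightly correlated *core*, the panels
   are re-derived on the cores, and the procedure recurses until no robust
   split remains. The recursion depth is data-determined, so the number of
   subtypes is an output, not an input.

A fitted tree doubles as a predictor: each core group gets an assignment
radius, and a new sample descends the tree as long as its mean correlation
distance to a core falls inside that group's radius.

## The bimodality screen

For a gene's expression vector \(X\) the package computes

\[
\sigma \;=\; \frac{\mathrm{Var}(X)}{\big(\mathbb{E}\,|X - \mathbb{E}X|\big)^{2}},
\]

with population (divide-by-\(n\)) moments. \(\sigma\) is dimensionless and
invariant under affine rescaling of \(X\), so it compares genes regardless of
their dynamic range. Calibration values: \(\pi/2\) for a Gaussian, 2 for a
biexponential (Laplace). Well-separated two-component mixtures push
\(\sigma\) *below* the Gaussian value — mass moves away from the overall mean
into two lumps, inflating the mean absolute deviation faster than the
standard deviation — so the genes with the smallest \(\sigma\) are the
bimodality candidates. Unlike kurtosis, \(\sigma\) uses no moment beyond the
second, which matters when each gene offers only ~200 noisy values.

```{r sigma-calibration}
set.seed(1)
sigma_stat(rnorm(1e5))$sigma          # ~ pi/2 = 1.5708
sigma_stat(rexp(1e5) - rexp(1e5))$sigma  # Laplace: ~ 2
```

Before evaluating \(\sigma\), extreme outliers more than `outlier_sd = 8`
standard deviations from the gene's mean are discarded in a single pass
(mean and SD computed once; the rule is not iterated). The screen keeps the
`n_sigma_genes = 60` smallest-\(\sigma\) genes after removing genes on
excluded chromosomes (default `"Y"`): a block of tightly correlated,
strongly bimodal Y-chromosome genes simply partitions patients by sex and
must not masquerade as a tumor subtype. When no annotation is available an
explicit `exclude_genes` list serves the same purpose.

## Persistence with a minimum component size

Both gene grouping and sample bisection run the same sweep. Points (genes or
samples) at correlation distance \(d = 1 - r_{\mathrm{Pearson}} \in [0, 2]\)
are connected when \(d < r_c\) (strictly), and \(r_c\) sweeps upward. The
package records the full merge tree (a union-find pass over edges sorted by
distance) and derives from it:

* **Barcodes** (`barcode()`): a component is awarded a bar only once it holds
  `n_min` members — each simplex's filtration time is promoted to the time
  its component reaches `n_min` elements — so sub-scale fragments never
  appear. Birth is that radius; death is absorption into an elder component.
  With `n_min = 1` this is exactly single-linkage persistence, which the
  tests exploit as an oracle (`hclust` merge heights).
* **Component queries** (`components_at()`): memberships at a fixed cutoff,
  each member annotated with the radius at which it joined the surviving
  lineage. This *join order* is the pipeline's coherence ordering: early
  joiners are the most tightly correlated members, and heat maps and core
  trimming both consume it.
* **Cutoff selection** (`pre_merge_cutoff()`): the two most persistent bars
  are taken at maximal membership "just prior to combining". Because edges
  require `d < r_c` strictly, evaluating the membership *at* the merge radius
  itself excludes the joining edge while including everything before it, so
  the function returns the merge radius. This resolves, in one convention,
  the question of whether membership is read off exactly at or just below
  the combining radius.

Ties in the sweep are ordered by (radius, smaller vertex indices), and the
elder rule is extended to size-constrained bars (earlier `n_min`-birth
survives; ties fall back to the smallest member index), making every run
bit-reproducible.

The `homology` layer generalizes the component count: `rips_complex()`
builds the flag complex of the threshold graph up to dimension 3, and
`betti_numbers()` computes \(b_0, b_1, b_2\) by exact GF(2) boundary-matrix
rank reduction. Betti numbers over GF(2) are exactly the dimension counts
the pipeline interprets (components, loops, voids); no torsion bookkeeping
is needed, and the canonical examples (figure-eight: \(b_1 = 2\);
octahedral sphere: \(b_2 = 1\); 7-vertex torus: \(1, 2, 1\)) are exact unit
tests rather than approximations. Only \(b_0\) participates in
partitioning; \(b_1, b_2\) document the machinery and support the geometric
generators.

## Panels, bisection, cores, recursion

`build_panels()` takes the top-2 persistent gene components and keeps the
first `n_g = 15` genes to join each — truncation stabilizes the panel
against stragglers that drift in near the merge radius. `bisect_samples()`
repeats the sweep on samples over the 30 panel genes with
`n_min_samples = 10`.

Core trimming makes a visual practice quantitative. The original procedure
kept the "left part of the heat map" — the early joiners — by inspection.
Here `trim_to_core()` admits members in join order and accepts a candidate
iff its mean correlation distance to the already-admitted members is at most
`theta = 0.5`; `core_fraction` (keep the first fraction of joiners) is the
simpler alternative, and exactly one rule is active. The default
`theta = 0.5` is a declared convention: half the correlation-distance range
between perfect coherence (0) and no correlation (1). It is deliberately
permissive — on clean planted data the admission rule keeps whole groups —
while still rejecting samples that are uncorrelated with the group
signature, and decreasing `theta` can only shrink a core (a tested
monotonicity).

`refine_panels()` then re-runs the *entire* gene-selection stage — sigma
screen over the full gene universe, not just the previous panels — on the
core samples alone. Re-screening from scratch matters: genes that separate
the cores sharply may be invisible in the full cohort, and conversely. The
same logic drives the recursion (`hierarchical_partition()`): each core
becomes a node, is re-screened, re-paneled and re-bisected, and a branch
ends when fewer than two qualifying bars exist, a trimmed core falls below
`n_min_samples`, or too few genes have a defined statistic. The 8-SD
outlier rule is re-applied uniformly within every subgroup.

## The prediction model

`fit_subtype_model()` stores, per split and core group, the group's panel
profiles and its **assignment radius**: the maximum over core members of the
member's leave-one-out mean correlation distance to the rest of the group.
Every core member therefore lies within its own radius, with equality for
the extremal member. `predict()` walks a query down the tree under a strict
`<` rule; below both radii it takes the nearer group and flags the call
ambiguous (a case the assignment rule must decide somehow; nearest-group is
the least-surprising convention), and below neither it stops, reporting the
deepest group reached or `"unassigned"`. Strictness is a feature: on planted
data the tests require *zero* false assignments while tolerating
unassignment, mirroring the intended clinical posture. The reported
dispersion alongside each mean distance is the standard deviation of the
per-core-member distances — a convention, documented as such. A `relax`
multiplier (> 1) inflates all radii for exploratory use.

## What the generator emulates — and what it does not

`planted_design()` encodes the statistical structure the pipeline assumes:

* **Marker modules** with per-subtype mean shifts of `effect_size = 2`
  against `noise_sd = 0.5` (a marginal mixture separation of 4 noise SDs,
  comfortably bimodal), plus a shared latent factor per module
  (`module_loading = 0.4`) inducing within-module correlation of ~0.8 —
  the minimal mechanism for "genes coherent because they share a
  subnetwork". Two anti-correlated modules per split give the two-panel
  geometry the sweep expects.
* **Hierarchy**: the default three subtypes `c(A1 = 30, A2 = 30, B = 40)`
  make the sibling pair separable from the outgroup at the root, while the
  `A1`/`A2` contrast is zero on `B` — so second-level markers are weakly
  trimodal in the full cohort and only become cleanly bimodal after the
  first bisection, exactly the regime in which re-screening inside the
  recursion is necessary. Cohort and group sizes are of the order of the
  motivating study's 182-sample cohort with 60/44 cores, scaled to keep the
  full test suite fast.
* **A sex-linked confounder block** (6 correlated genes, bimodal by a
  random binary sex covariate, annotated to chromosome Y) that the screen
  must exclude by annotation, not by statistics — it is statistically
  indistinguishable from a real subtype module.
* **Background genes** as unit-variance Gaussian noise.

Not emulated: platform/probe-level noise, batch effects, missing-value
patterns of real arrays, correlated background structure, or unbalanced
label noise. Passing the planted-recovery tests therefore demonstrates the
algorithm's correctness under its own assumptions, not performance on any
real cohort; the headline quantities of real-data analyses (specific gene
lists, 84/76-type partition sizes) depend on the external matrices and are
out of scope here.

Geometric generators (`simulate_point_cloud()`) provide clusters, circle,
figure-eight and torus clouds for the persistence and homology tests.

## Numerical choices and degenerate inputs

* Population moments throughout \(\sigma\); the estimator choice cancels in
  the ratio asymptotically and keeps the two calibration values exact.
* Pearson correlations use pairwise-complete observations; items with zero
  variance (or < 3 finite values) cannot be placed in correlation space and
  are excluded with a warning rather than silently imputed.
* Distances are clamped to [0, 2] against floating-point drift; the
  diagonal is exactly 0.
* All-identical values make \(\sigma\) undefined (0/0) and raise a classed
  error; fewer than 3 retained values likewise.
* `n_min` larger than the item count yields an empty barcode, not an error;
  "no robust partition" is a classed condition (`topo_no_partition`), which
  the recursion converts into a leaf and the CLI into exit code 2.
* Every stochastic function takes an explicit seed and restores the RNG
  state (`withr::with_seed`); identical inputs give byte-identical outputs.

## Problem sizes in the test suite

The suite generates all data programmatically: cohorts of ~100 samples by
~106 genes, 20 seeds for the recovery and prediction protocols, Monte-Carlo
calibration at 10^6 draws, and 200 cloud/threshold instances for the oracle
equivalence checks. These sizes were chosen so that each property is
statistically unambiguous at desk scale.

## Known limitations

* The sweep is exact but dense (all pairwise distances); it is intended for
  point clouds up to a few hundred items, which covers gene panels and
  cohort sizes of interest. No landmark/approximate Rips construction is
  provided.
* Persistent \(b_1\)/\(b_2\) barcodes are not computed — persistence is
  tracked for components only, matching what partitioning needs.
* The trimming threshold `theta` is a convention, not an estimate; analyses
  of real cohorts should report it alongside results.
* Exclusion of confounder blocks is annotation-driven; in the absence of
  annotation, an unnoticed technical covariate (sex, batch) can surface as
  the dominant split, exactly as a Y-chromosome block would.
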