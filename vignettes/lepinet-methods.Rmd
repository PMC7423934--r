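---
title: "Methods: spectral-count networks and differential analysis in lepinet"
author: "lepinet maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral-count networks and differential analysis in lepinet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lepinet)
```

## Scope and data model

`lepinet` implements a proteogenomic comparison pipeline for small
multi-group cohorts profiled by label-free spectral counting, modelled on
the three early lung adenocarcinoma subtypes AIS, MIA and LPA (5, 5 and 4
patients, each sample acquired in triplicate LC-MS/MS runs). The primary
input is a protein x run matrix of spectral counts (SpC): the number of
tandem MS/MS spectra assigned to a protein, a count-valued proxy for
abundance. Counts are held in a `SpectralCountSet` (a
`SummarizedExperiment` whose `colData` maps runs to biological samples);
the subtype assignment lives in a `GroupDesign`, which also derives
one-vs-rest binary trait vectors used as "clinical traits" downstream.

Replicate runs are combined per sample before any analysis. The default is
summation, which conserves total counts and keeps them integral -- the
G-test below is count-based by construction, so it always operates on raw
aggregated integers. `mean_round` (half-up) is available where run-depth
imbalance is a concern.

Two normalizations feed the non-count analyses. `total_count` divides each
sample column by its total (a compositional share; columns sum to 1).
`log2_total`, the default for correlation analysis, is
`log2(1 + 1e4 * share)`: a depth-stabilized log scale on which Pearson
correlation is meaningful across samples of unequal depth. The upstream
acquisition does not dictate a normalization, so both are explicit,
tagged in the result (`NormalizedMatrix`), and stated in every manifest.

## Presence filtering

A protein is *characteristic* of a subtype when it is observed in more
than three samples of that subtype, i.e. `SpC > 0` in at least
`minSamples = 4` samples. Published statements of this rule sometimes
print `SpC >= 0`, which would admit every protein in every group; we treat
that as a typo for presence, but keep the literal reading behind
`rule = "nonneg"` so both variants are computable. The characteristic set
is monotonically non-increasing in `minSamples` (a property the tests
exercise), and a group smaller than `minSamples` yields an empty set with
a warning rather than an error.

## Pairwise G-statistics with Williams' correction

For each protein and each pair of groups A, B a 2x2 table is built from
summed counts: the protein's counts in A and B on one row, the remaining
counts of each group (group total minus the protein) on the other. This
"protein vs the rest of the proteome" construction is the canonical form
for spectral-count G-tests. The statistic is the log-likelihood ratio

$$G = 2 \sum_{cells} O \, \ln(O/E), \qquad 0 \ln(0/E) := 0,$$

with expecteds from the margins, divided by Williams' correction

$$q = 1 + \frac{(N/R_1 + N/R_2 - 1)(N/C_1 + N/C_2 - 1)}{6N},$$

and referred to a chi-square with 1 df. Since $q \ge 1$, the correction
can only shrink $G$ and enlarge $p$, which is what makes the test usable
at small counts. Tables with a zero row or column margin (e.g. a protein
absent from both groups) are degenerate and short-circuit to $G = 0$,
$p = 1$ rather than erroring -- zeros are routine in spectral counting.

A protein is *significant to group g* when three criteria hold
simultaneously:

1. presence: `SpC > 0` in at least 60% of g's samples;
2. dominance: g's *relative abundance share* exceeds 50%, where the share
   is g's mean normalized abundance divided by the sum of the group means
   (shares sum to 1 across groups, so >50% identifies the dominant group
   among three);
3. significance: BH-adjusted q < 0.05 in *both* pairwise comparisons of g
   against the other groups.

Two genuinely open choices are parameterized rather than guessed silently.
The BH family defaults to all (protein, pair) p-values pooled -- the more
conservative and reproducible family -- with per-pair adjustment behind
`bhFamily = "per_pair"`. The share criterion defaults to `total_count`
normalization; any tagged normalization can be substituted.

## Co-expression networks

The network pipeline follows the weighted co-expression (WGCNA) recipe:
Pearson correlation of normalized profiles, soft-thresholded adjacency,
topological overlap, average-linkage clustering of `1 - TOM`, dynamic tree
cut, module summarization, module-trait correlation.

**Adjacency.** The default transform is the *signed* network
$a_{ij} = ((1 + r_{ij})/2)^\beta$ with $\beta = 10$: anticorrelated
proteins are unconnected. Reports of this style of analysis sometimes
state the similarity as $(1 - r)/2$, which maps perfect correlation to
zero; that is almost certainly a sign slip, but the transform is preserved
verbatim behind `mode = "dissimilarity"` so the literal computation
remains available. `unsigned` ($|r|^\beta$) is also provided. The diagonal
is set to 1 by convention, but connectivity $k_i = \sum_{j \ne i} a_{ij}$
always excludes the self term.

**Soft-threshold choice.** `softThresholdFit()` reports, per candidate
$\beta$, the signed scale-free fit index: connectivities are binned
(10 equal-width bins of $\log_{10} k$), $\log_{10}$ frequency is regressed
on $\log_{10}$ bin mean, and the index is $-\mathrm{sign}(slope) \cdot
R^2$. The recommendation is the smallest $\beta$ reaching 0.8, else the
maximizer. A degenerate (equal-connectivity) network reports NA.

**TOM.** For $i \ne j$,
$\mathrm{TOM}_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 -
a_{ij})$ with $\ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}$;
$\mathrm{TOM}_{ii} = 1$; a zero denominator yields 0. The complete
unit-weight graph gives an all-ones TOM and the 3-node star with
half-weight spokes gives $\mathrm{TOM}_{12} = 0.5$ -- both closed forms
are asserted in the tests.

**Dynamic tree cut.** No reference implementation of the dynamic hybrid
cut is bundled with this package's dependencies, so `cutreeDynamicHybrid()`
is authored here. Merge heights are normalized to the tree top, and two
thresholds derive from `deepSplit` $\in \{0,\dots,4\}$: a core-scatter
ceiling from $\{0.64, 0.73, 0.82, 0.91, 0.95\}$ and a minimum gap
$(1 - \mathrm{ceiling}) \cdot 3/4$, both calibrated to the interval
between the 5th percentile of merge heights and 1 so they adapt to where
the dissimilarities actually live. Merges are processed bottom-up: a
growing branch absorbs singletons and side-branches smaller than
`minModuleSize` (average-linkage trees attach module members one leaf at
a time, so accretion -- not a node-local split test -- is what recovers
them); when two branch-like clusters meet, each one whose core scatter
(mean internal merge height) is under the ceiling and whose gap to the
merge height is at least the minimum is finalized as a module. Leaves
covered by no finalized branch keep label 0; there is no post-hoc
reassignment (PAM-style) stage, so unassigned really means unassigned.
Labels are renumbered by decreasing size. At `deepSplit = 4` the criteria
are permissive and unstructured background fragments into many small
modules -- consistent with tens of modules being reported from real
~2,000-protein cohorts -- which is why module-recovery benchmarks below
score the planted proteins rather than the background.

**Module summary and traits.** A module is summarized by its
*eigen-protein*: the member with the highest intramodular connectivity
$k^{IM}_i = \sum_{j \in m, j \ne i} a_{ij}$ (ties broken by protein id).
The classical first-principal-component eigengene is available as
`moduleSummary(..., method = "pca")`, but the hub definition is the
default because it is the stated summary of the analysis this package
operationalizes. Module-trait statistics are Pearson correlations between
the eigen-protein profile and each one-vs-rest trait vector, with
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n - 2$ df (two-sided) and BH adjustment
per trait across modules (pooled adjustment behind a flag). Modules are
flagged at $|r| > 0.5$ and $q < 0.05$.

## Hub ranking by maximal clique centrality

For a protein-protein interaction graph (read from a STRING-style edge
list, with a score filter defaulting to the medium-confidence 0.400
convention at load), the MCC score of a node is
$\sum_{C \ni v} (|C| - 1)!$ over maximal cliques $C$. Maximal cliques come
from igraph's pivoted Bron-Kerbosch enumeration; an isolated node sits in
one singleton clique and scores $0! = 1$, so scores are always positive.
Ranks break ties by degree, then id, so top-k lists are reproducible. The
test suite checks MCC against an exhaustive subset-search oracle on 200
random graphs of up to 10 nodes, plus the $K_n \to (n-1)!$ closed form.

## Genomic alteration burden

Copy-number states use strict thresholds: loss is CN < 2 (diploid is not a
loss), gain is CN > 2.5 by default -- the gain cutoff has no published
anchor in the analyses this package reproduces, so it sits behind a flag.
The burden comparison between two groups is a two-sided Mann-Whitney test
on per-sample loss counts. Because burden counts tie heavily at these
sample sizes and the standard exact algorithm refuses ties,
`compareBurden()` enumerates all $\binom{n_A + n_B}{n_A}$ label
assignments of the midranks whenever both groups have at most 6 samples,
doubling the smaller tail probability (capped at 1). A Welch t-test is
available behind a flag. All-identical burdens return p = 1 with a
warning.

## The synthetic cohort generator

`simulateCounts()` emulates the study conditions end to end so every
stage is testable without any external download: 3 groups of 5/5/4
samples, 2,000 proteins, triplicate runs, and an expected depth of
$10^4$ counts per run. Per-protein baseline log-abundance is
N(0, 1) (about a 10-fold typical dynamic range). Each planted module
carries a per-sample latent factor; members add `loading * factor` to
their log-abundance. Trait-free modules draw factors N(0, 1); a module
linked to a group draws N(2 * [sample in group], 1/3) -- a modest ~6-fold
abundance change at loading 0.9, but with low within-group variability,
which puts the *observed* eigen-protein vs trait correlation near 0.9,
the range reported for significant trait-linked modules in early lung
adenocarcinoma proteomes. (Raising the mean shift instead inflates
abundance swings by orders of magnitude and distorts the compositional
structure; low within-group noise is how strong module-trait correlations
arise in practice.) Planted differential proteins add `log(fold)` in
their target group. Expected counts are `depth * softmax(log-abundance)`
per sample -- spectral counts are compositional -- and observed counts
are drawn per replicate from a negative binomial with dispersion 0.2
(variance $\mu + 0.2\mu^2$, typical overdispersion) or, for clean
distributional oracle checks such as type-I-error calibration, a Poisson.

What the generator does *not* emulate: peptide-level identification and
shared-peptide ambiguity, structured missingness beyond sampling zeros,
batch or acquisition-order effects, and correlated background (background
proteins are independent given depth). Tests passing on this generator
therefore demonstrate correctness of the statistical machinery under its
stated model, not robustness to those real-data phenomena.

`simulateNetwork()` provides the graph-side fixtures: planted complete
subgraphs on disjoint node sets over a sparse background, with the
planted members recorded as intended hubs.

## Benchmark configurations and numerical choices

The packaged benchmarks run at fixed, stated sizes:

* Null calibration: 2,000 proteins, two groups of 5, Poisson noise, one
  pair of groups; the Williams-corrected test's rejection rate at
  $\alpha = 0.05$ is required to sit within 3 binomial SEs of 0.05, and
  pooled BH at q < 0.05 to yield at most one discovery.
* Module recovery: 20 seeds of the 3-module generator (size 30, loading
  0.9, one module LPA-linked) at the full 2,000-protein scale. Recovery is
  scored as the adjusted Rand index over the 90 planted proteins --
  background has no true module structure to score, and `deepSplit = 4`
  legitimately fragments it. The trait check asks that the recovered
  module carrying the planted LPA proteins attain the top |r| among all
  (module, trait) statistics.
* The proteome-scale benchmarks were kept at 2,000 proteins deliberately:
  at a few hundred proteins a 30-protein module is a tenth or more of the
  whole composition and softmax coupling dominates every module-trait
  correlation, a regime real ~2,000-protein cohorts are not in.

Other numerical conventions: half-up rounding in `mean_round`; all
matrix I/O is UTF-8 TSV with '.' decimals and exact round-tripping;
readers reject malformed numerics instead of coercing; `hclust`'s
deterministic tie handling is relied on for reproducible trees; eigen- and
hub-protein ties break lexicographically; clique enumeration refuses
graphs above a configurable size bound instead of hanging. Cohort
descriptive SDs use divisor $n$ (population form) by default because the
printed per-patient values of the reference cohort reproduce the printed
SDs only under that form; the $n-1$ form is behind `sd = "sample"`.

## Known limitations

* The dynamic cut has no PAM stage, so borderline leaves stay unassigned
  where the reference method might rescue them; module *cores* are
  recovered robustly but per-module membership is conservative.
* The G-test treats pooled group counts as one table per protein; it does
  not model between-sample biological variability within a group (no
  dispersion term), which is faithful to the method it reproduces but
  anticonservative under strong overdispersion.
* Relative abundance shares and the BH family are explicit parameter
  choices where the reproduced analysis left them unstated; defaults are
  documented above and in the function help.
* MCC uses floating-point factorials; cliques beyond ~170 members would
  overflow, far above anything a score-filtered PPI neighbourhood
  produces.
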