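# lepinet

Proteogenomic comparison of early lung adenocarcinoma subtypes — AIS
(adenocarcinoma in situ), MIA (minimally invasive) and LPA (lepidic
predominant invasive adenocarcinoma) — from label-free spectral-count
proteomics, for small cohorts of the 5/5/4-patient scale where standard
large-cohort tooling is uninformative. The package is aimed at
computational proteomics practitioners who have a protein × sample
spectral-count matrix (plus, optionally, a PPI edge list and per-gene
copy-number calls) and want the full analysis chain as tested, scriptable
functions.

## What it computes

* **Presence filtering** — a protein is *characteristic* of a subtype
  when SpC > 0 in more than three samples of that subtype.
* **Differential analysis** — pairwise G-tests on 2×2 tables (protein
  counts vs remaining counts per group), with Williams' correction
  G<sub>adj</sub> = G / q, q = 1 + (N/R₁ + N/R₂ − 1)(N/C₁ + N/C₂ − 1)/(6N),
  Benjamini–Hochberg control, and a three-part per-group significance
  rule (presence ≥ 60 %, relative-abundance share > 50 %, q < 0.05 in
  both pairwise tests).
* **Co-expression modules** — weighted network analysis: signed adjacency
  ((1 + r)/2)^β with β = 10, topological overlap, average-linkage
  clustering of 1 − TOM, a dynamic hybrid tree cut
  (deepSplit 0–4, minimum module size 10), hub *eigen-proteins*
  (highest intramodular connectivity), and module–trait correlation
  against one-vs-rest subtype traits with BH correction and an
  |r| > 0.5 screen.
* **Hub ranking** — maximal clique centrality, MCC(v) = Σ_{C∋v}(|C|−1)!
  over maximal cliques, on STRING-style edge lists (score ≥ 0.400 by
  default).
* **Copy-number-loss burden** — per-sample counts of genes with CN < 2,
  compared between groups by an exact (full-enumeration, tie-safe)
  Mann–Whitney test.
* **Cohort statistics** — per-group mean ± SD (population form) and
  one-way ANOVA, reproducing the printed clinical summary of the
  14-patient reference cohort bundled in `inst/extdata/luad_cohort.tsv`.
* **Synthetic cohorts** — a seeded generator with planted co-expression
  modules, trait links and differential proteins, so the entire pipeline
  is testable end to end with no external data.

## Worked example

```r
library(lepinet)

sim <- simulateCounts(simSpec(nProteins = 2000, seed = 11,
    modules = list(list(size = 30, group = "LPA", loading = 0.9)),
    differential = list(list(n = 10, group = "AIS", fold = 8))))
agg <- aggregateReplicates(sim$counts)       # triplicate runs -> samples
res <- significantProteins(agg, sim$design)
res
#> DiffResult: 2000 proteins, 3 group pairs
#>   significant proteins: AIS=12, LPA=30, MIA=2

nm  <- normalizeCounts(agg, "log2_total")
fit <- buildCoexprModel(nm, sim$design)      # beta=10, deepSplit=4
fit
#> CoexprModel: 2000 proteins, 110 modules (beta = 10 , mode = signed )
#>   module sizes: 83 39 39 38 38 34 29 29 ...
#>   unassigned: 4

head(traitStats(fit)[order(-abs(traitStats(fit)$r)), 
                     c("module", "trait", "r", "p", "q")], 3)
#>  module trait          r            p            q
#>       7   AIS  0.9749163 3.407086e-09 3.747794e-07
#>       1   LPA  0.9640124 2.901856e-08 3.192042e-06
#>      77   AIS -0.8447624 1.433638e-04 7.885009e-03
```

Reading the output: the 30-protein planted LPA module is recovered as
module 1 and correlates with the LPA trait at r = 0.96 (BH q ≈ 3×10⁻⁶);
its members are also flagged differential to LPA (they are genuinely
upregulated there), alongside the 10 planted 8-fold AIS proteins — which,
sharing a group-specific shift, additionally surface as an AIS-correlated
module (module 7). The G-test machinery itself is exact and
hand-checkable:

```r
gStatistic(matrix(c(10, 90, 0, 100), 2))
#> $G 14.3895   $q_williams 1.0501   $G_adj 13.7026   $p 0.000214
```

A thin command-line wrapper over the same functions ships in
`inst/scripts/lepinet` (subcommands `filter`, `gstat`, `wgcna`, `hubs`,
`cnv`, `simulate`, `cohort-stats`; global `--config`, `--seed`,
`--out-dir`, `--log-level`). The methods vignette
(`vignettes/lepinet-methods.Rmd`) documents the models, parameter
defaults and numerical conventions.

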