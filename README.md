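# assemblytrace

Community-assembly analysis for microbiome count data sampled along a
press-disturbance chronosequence — for microbial ecologists asking whether
*selection*, *dispersal*, or *drift* explains why disturbed communities
diverge and recovering ones converge.

The package bundles, behind one `SummarizedExperiment`-based container:

* **Diversity** — richness, Pielou's evenness, Faith's whole-tree
  phylogenetic diversity; Bray-Curtis; unweighted and weighted UniFrac in
  normalized and non-normalized (raw) forms, from a reusable branch
  decomposition of the phylogeny.
* **Sloan neutral community model** — occurrence frequency vs.
  metacommunity abundance. With detection limit `d = 1/N`, the neutral
  expectation is `f_pred(m) = 1 − I_d(Nmp, Nm(1−p))` (regularized
  incomplete beta); `m` is fitted by least squares, taxa are partitioned
  against a 95% binomial envelope, and the immigration estimate is reported
  on both the conventional beta scale and the equivalent per-event urn
  probability (`mMoran`).
* **Beta-null deviation modeling** — abundance-based nulls preserving each
  sample's richness and depth (occupancy-weighted occurrence,
  regional-abundance-weighted allocation), deviations
  `d_obs − mean(d_null)` for Bray-Curtis and — the phylogenetic extension —
  weighted UniFrac, with per-class contrasts and temperature trajectories.
* **Multivariate statistics** — PERMANOVA, multivariate dispersion (spatial
  medians), PCoA, environmental vector fitting, temperature-partialled
  ordination, and Mantel tests (delegating to `vegan` throughout).
* **Dominance analysis** — per-sample top-10 taxa, their class-wide union,
  occurrence and abundance shares, and phylum-level summaries.
* **Synthetic ground truth** — a compiled urn simulator (neutral and
  thermal-niche variants), a divergent-dominants generator emulating
  priority effects, and a full 18-soil chronosequence scenario (9
  fire-affected soils at 21–58 °C, 7 recovered and 2 reference soils at
  12–15 °C) with tree, taxonomy and soil chemistry.

## Worked example

```r
library(assemblytrace)

ce  <- simulateChronosequence(seed = 1)   # 18 soils, 400-taxon pool
res <- runChronosequenceAnalysis(ce, nIter = 199, seed = 1)

res$permanova[c("pseudoF", "r2", "p")]
#> $pseudoF [1] 6.834331
#> $r2      [1] 0.4767806
#> $p       [1] 0.000999001

res$dispersion$medianDispersion
#> fire_affected     recovered     reference
#>    0.42124006    0.08673914    0.06156212

res$betaNull$bray_curtis$groupMeans
#> fire_affected     recovered     reference
#>    0.48371817    0.01089256    0.02063065

res$betaNull$metricCorrelation$r
#> [1] 0.6097457

length(res$topK$fire_affected$union)   # out of 90 possible
#> [1] 36
```

Read: fire classification explains ~48% of the weighted-UniFrac variance
(PERMANOVA p = 0.001); fire-affected soils are several times more dispersed
than recovered ones; their Bray-Curtis beta-null deviations sit far above
the recovered class (which is close to the null expectation, as a neutrally
assembled class should be); Bray-Curtis and weighted-UniFrac deviations
agree (r = 0.61); and the nine hot soils collectively hold 36 distinct
top-10 taxa where maximally convergent communities would hold 10 — the
divergent-dominants signature. The per-class Sloan fits
(`res$neutral$recovered`, `res$neutral$fire_affected`) show a lower
immigration estimate in the fire-affected class.

The methods vignette (`vignettes/community-assembly-methods.Rmd`) documents
the models, parameter choices, null-model construction, and known
limitations.

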