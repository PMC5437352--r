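Package: assemblytrace
Title: Community Assembly Analysis for Disturbance Chronosequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers the community assembly processes (selection, dispersal,
    drift) acting on microbial communities sampled along a press-disturbance
    chronosequence. Provides a SummarizedExperiment-based container for
    sample-by-taxon count tables with an attached phylogeny, taxonomy and
    sample metadata; alpha diversity (richness, Pielou's evenness, Faith's
    whole-tree phylogenetic diversity); beta diversity (Bray-Curtis,
    unweighted and weighted UniFrac in normalized and non-normalized forms);
    fitting of the Sloan neutral community model with taxon-level neutral
    envelopes; abundance-based beta-null deviation modeling for Bray-Curtis
    and weighted UniFrac; distance-based multivariate statistics (PERMANOVA,
    multivariate dispersion, PCoA, environmental vector fitting,
    temperature-partialled ordination, Mantel tests); and dominance and
    phylum-level summaries. A forward urn simulator with neutral, thermal
    niche-filter and divergent-dominant scenarios generates communities with
    known assembly processes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ape,
    vegan,
    phangorn,
    withr,
    S4Vectors,
    SummarizedExperiment,
    biomformat
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    picante,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
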