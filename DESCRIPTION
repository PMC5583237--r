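Package: lodemap
Title: Gene-Based Linkage Map Construction with LODE Marker Placement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction of genetic linkage maps from multi-family full-sib
    pedigrees with grandparent-traced phase, in the workflow used for SNP-array
    mapping in aquaculture species. Provides genotype quality-control ledgers
    (array conversion/validation accounting and in-silico SNP discovery
    filtering), phase-known two-point linkage analysis with Kosambi map
    distances, LOD-threshold linkage grouping and hierarchical framework
    ordering, sex-specific map recalculation, recombination-heterogeneity and
    segregation-distortion tests, two-locus EM linkage-disequilibrium
    estimation, locus ordering by disequilibrium (LODE) placement of orphan
    markers, genome-coverage estimation, and cross-map synteny comparison via
    Oxford grids. A pedigree/genotype simulator with known truth (map, phase,
    founder LD, distortion) supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
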