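Package: cpmapr
Title: Linkage Maps for Cross-Pollinated Populations and Alien
    Introgression Detection from SNP Array Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds genetic linkage maps for outbred F1 (cross-pollinated,
    "CP") mapping populations genotyped on a SNP array, and identifies
    alien chromosome addition and substitution lines in a hexaploid wheat
    background. Provides SNP performance categorisation and call-rate
    filtering, CP segregation-pattern classification and segregation
    distortion tests, two-point maximum-likelihood recombination-fraction
    and LOD estimation across testcross, intercross and mixed marker
    pairs, LOD-threshold linkage grouping, marker ordering with
    co-segregation binning and Kosambi map distances, assignment of
    linkage groups to wheat homoeologous groups from alignment hits with
    collinearity-block and rearrangement detection, and sliding-window
    heterozygosity/missingness profiling to call added and substituted
    chromosomes in wheat-wild relative derivative lines. A synthetic-data
    module simulates CP crosses, marker-to-wheat hit tables and
    introgression-line genotypes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse,
    knitr
Config/testthat/edition: 3
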