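Package: plastohotspot
Title: Mutational Hotspot Ranking and Marker Selection from Comparative Plastome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of annotated quadripartite plastomes:
    quadripartite length accounting and AT content, pairwise InDel-event
    extraction and its correlation with plastome-size variation, a sequence
    variability (SV) statistic for ranking mutational hotspots among syntenic
    intergenic and intronic loci, polymorphic chloroplast microsatellite
    (cpSSR) detection, and exhaustive multi-hotspot combination analysis
    scored by mean bootstrap support of distance trees. Includes a synthetic
    plastome generator with known ground truth (tree, planted hotspots,
    InDels, SSR slippage, NDH gene loss) so the whole pipeline is testable
    without any sequence download.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
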