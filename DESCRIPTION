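Package: coxflow
Title: Community Ecology of Soil Carbon Monoxide Oxidizing Bacteria from
    coxL Marker Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analytical chain linking the structure of soil carboxydovore
    (carbon monoxide oxidizing) bacterial communities, profiled through the
    coxL gene encoding the large subunit of aerobic CO dehydrogenase, to
    high-affinity CO uptake activity. Classifies coxL sequences into
    functional type I, hypothetical type II and atypical type II groups from
    the translated active-site signature; calibrates a species-level coxL
    OTU similarity threshold against paired 16S rRNA similarities with a
    prediction interval; clusters sequences into OTUs, rarefies libraries
    and computes Shannon/Simpson diversity and unweighted UniFrac distances
    with UPGMA/jackknife support; estimates apparent first-order CO uptake
    rate constants from flask headspace time series and converts them to
    soil-mass-normalized and cell-specific rates; quantifies coxL gene
    copies from qPCR standard curves and brackets them with theoretical
    carboxydovore population bands; and relates Hellinger-transformed OTU
    profiles to standardized soil variables by redundancy analysis with
    forward selection and permutation tests. A synthetic-data module
    generates every input class with known ground truth for parameter
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    picante,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
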