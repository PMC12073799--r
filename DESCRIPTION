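Package: ccdnet
Title: Structural Connectome Analysis for Mouse Models of Corpus Callosum Dysgenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and compares weighted structural brain connectomes for mouse
    models of complete and partial corpus callosum dysgenesis (CCD). Provides a
    synthetic cohort generator emulating normal, complete-CCD, partial-CCD and
    virtually callosotomized 76-region mouse brain networks; connectome
    construction from seed connectivity maps with fractional-anisotropy edge
    weighting; consensus connectomes; proportional sparsity thresholding with
    area-under-the-curve summaries of weighted graph metrics; Louvain community
    detection with resolution parameter, consensus partitions, participation
    coefficients and hub classification; the network-based statistic (NBS) with
    permutation family-wise error control; edge-weight variability and pairwise
    network similarity statistics; and a novel-connection discovery rule for
    low-penetrance tracts such as the sigmoid bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
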