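Package: gravispread
Title: Gravity-Model Centralities and SIR Spreading Evaluation for
    Influential-Node Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies influential spreaders in undirected, unweighted
    networks with the H-index-based gravity centrality (HVGC), which combines
    a neighbourhood-mass index built from the H-index with Burt's structural
    hole constraint coefficient inside a distance-truncated gravity sum.
    Also provides ten baseline gravity-model centralities (G, G+, IGC, IGC+,
    LGM, GGC, KSGC, DKGM, MCGM, SEGM), a discrete-time SIR Monte-Carlo
    simulator estimating per-node spreading capacity, ranking-quality
    measures (Kendall's tau, top-k Jaccard similarity, monotonicity),
    plain-text edge-list input and output, synthetic graph generators, and a
    packaged ten-node worked-example network. All user-facing functions take
    a graph or edge-list data frame and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
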