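Package: allohubr
Title: Allosteric Hub Detection from Structural-Alphabet Encoded
    Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects allosteric hub fragments in proteins from molecular
    dynamics trajectories. Calpha trajectories are coarse-grained with a
    structural alphabet of four-residue prototype fragments (assigned by
    optimal Kabsch superposition), correlated motions are quantified as
    finite-size-corrected normalised mutual information between fragment
    columns of the encoded alignment, conformational substates are
    extracted from time-contiguous trajectory blocks via the covariance
    matrix overlap, and ensemble-averaged coupling networks of two
    liganded states are contrasted with a rank-sum/FDR difference-network
    analysis to rank hub fragments. Companion tools compute minimal
    allosteric communication pathways (Dijkstra), Schlitter
    configurational entropy, positional fragment entropy, allosteric
    coupling coefficients, and tolerated hub substitutions from a
    multiple sequence alignment. A fully seeded synthetic-data generator
    with planted couplings and regime switches supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tools,
    utils,
    yaml
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
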