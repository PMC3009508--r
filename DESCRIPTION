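Package: knotfold
Title: RNA Secondary Structure Prediction with Pseudoknots via Gap-Matrix
    Dynamic Programming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts RNA secondary structures including general pseudoknots
    with the one-hole gap-matrix dynamic programming scheme (the VX/WX
    triangular matrices plus the WHX, VHX, ZHX and YHX gap matrices) under
    base-pair maximization scoring. Provides three work-block execution
    strategies mirroring code, data and hybrid parallel decompositions of the
    WHX fill (C-Par, D-Par, H-Par) with a threshold scheduler, a per-matrix
    operation-count profiler, independent verification oracles (Nussinov
    maximum pairing, exhaustive grammar evaluation, brute-force maximum
    matching), layered dot-bracket and CT output, a synthetic sequence
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
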