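Package: convtree
Title: Exact Bayesian Inference on Sums of Discrete Variables via Probabilistic Convolution Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Exact posterior inference for graphical models whose shared
    evidence depends only on the sum (or an integer-weighted sum) of many
    discrete variables, the situation that arises in protein inference from
    shared peptides. Implements three exact engines over the same problem
    description: brute-force power-set enumeration, a quadratic
    forward-backward dynamic program over partial sums, and the probabilistic
    convolution tree, which passes FFT-convolution messages through a layered
    binary tree in sub-quadratic time and near-linear space. Includes the
    noisy-or peptide emission model used to build count-dependent
    likelihoods, a seedable random benchmark-problem generator, a JSON
    problem-file format, integer scaling nodes, cascaded adder trees with
    node-specific evidence, a two-dimensional variant, and non-probabilistic
    counting of integer tuples (coin-change and linear Diophantine counts).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
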