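Package: nestmax
Title: Maximum Nestedness of Bipartite Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the NODF nestedness metric (nestedness based on
    overlap and decreasing fill) for binary bipartite interaction
    matrices, such as plant-pollinator networks, and estimates the
    maximum NODF attainable by any feasible matrix with the same numbers
    of rows, columns and links (every row and column keeping at least one
    link).  Maximization is available by exhaustive enumeration, by a
    greedy link-placement heuristic, and by simulated annealing over
    single-link moves with an incremental NODF evaluator.  From an
    observed matrix and a maximum-NODF estimate the package derives the
    normalized nestedness NODF_n = NODF / max(NODF) and the combined
    statistic NODF_c = NODF_n / (C * log(S)), where C is connectance and
    S the geometric mean of the two guild sizes.  Includes matrix and
    edge-list readers, synthetic fixture generators, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
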