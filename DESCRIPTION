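Package: eminet
Title: Entropy and Mutual-Information Node Importance for Complex Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks nodes of directed or undirected, weighted or unweighted
    networks by the EMI score: Shannon entropies of the neighbours' degree
    and strength distributions (structural and interactive entropy) combined
    with a non-positive mutual-information correction that penalises
    redundant influence between adjacent nodes sharing neighbours. Includes
    the classical comparator centralities (degree, closeness, k-shell,
    betweenness, eigenvector, simplified PageRank), ranking-discriminability
    metrics (monotonicity, complementary cumulative rank distribution,
    top-k overlap), a Monte-Carlo susceptible-infected spreading simulator
    for seed-set influence, synthetic network generators, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
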