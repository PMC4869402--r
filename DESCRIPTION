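Package: grcs
Title: Minimum Local Parsimonious DCJ Scenarios with Colored Adjacencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes double cut and join (DCJ) rearrangement scenarios
    between two genomes with equal syntenic-block content that are both
    parsimonious (minimum length) and, among all minimum-length scenarios,
    use the fewest "rare" moves under a binary positional weight function.
    Adjacencies of the source genome carry color labels modeling positional
    constraints (for example spatial localities derived from chromatin
    conformation); a DCJ cutting two adjacencies of different colors is
    rare, all other moves are likely.  The optimum is obtained by solving
    Minimum Noncrossing Colored Partition on each component of the colored
    adjacency graph and a maximum-weight bipartite matching that decides
    which even-length paths to mix.  Includes exhaustive brute-force
    oracles, seeded random instance generation and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
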