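Package: echonet
Title: Entropy-Based Detection of Echo Chambers in Retweet and URL-Sharing Networks
Version: 0.1.0
Authors@R:
    person("echonet", "developers", email = "echonet@example.org", role = c("aut", "cre"))
Description: Detects echo chambers in social-media post datasets with a
    maximum-entropy null model. Fits the Bipartite Configuration Model (BiCM)
    to binary bipartite networks by constrained Shannon-entropy maximization,
    statistically validates monopartite co-occurrence projections with exact
    Poisson-binomial p-values under Benjamini-Hochberg false-discovery-rate
    control, extracts discursive communities (DiCo) by best-of-N Louvain plus
    two-phase majority label propagation on the retweet network, extracts news
    engagement communities (NEC) from the user-URL bipartite network, and
    reports echo chambers as NEC-and-DiCo co-members connected through
    retweets, with clustering-coefficient diagnostics, aggregated retweet
    flows and news-trustworthiness tallies. Includes a seeded synthetic
    dataset generator with planted ground truth and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
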