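Package: triomics
Title: Tripartite Multiomics Integration for Cytotoxicity Biomarker Nomination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates per-group differential gene, protein and metabolite
    calls into candidate cytotoxicity biomarkers. Screens gene/protein pairs
    with direction-consistent differential expression within a treatment
    group, maps pairs and differential metabolites onto a pathway knowledge
    base, detects enzyme-to-metabolite upstream-downstream relations by
    directed reachability over reaction graphs, assembles the relation links
    into a tripartite pair-metabolite-pathway network, ranks its connected
    subnetworks, extracts the top subnetwork's members as candidate
    biomarkers, and correlates per-group integration summaries with a cell
    proliferation series. Includes a synthetic-data generator with planted,
    recoverable ground truth for end-to-end benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
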