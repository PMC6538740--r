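Package: netpharm
Title: Network Pharmacology and Downstream Omics Statistics for Herbal
    Combination-Therapy Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for traditional-medicine network pharmacology
    and its downstream preclinical statistics: ADME screening of herbal
    compound tables by oral bioavailability and drug-likeness thresholds,
    construction and intersection of compound-target and protein-protein
    interaction networks, centrality-based hub extraction at network
    medians, hypergeometric over-representation analysis with
    Benjamini-Hochberg correction, xenograft tumour-growth-inhibition
    analytics, 16S alpha-diversity and rank-sum differential abundance,
    and PLS-DA/VIP metabolite selection with Venn set logic. A seeded
    synthetic-data module generates every input with planted ground truth
    for parameter-recovery and null-calibration testing.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
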