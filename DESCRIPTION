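Package: netpharm
Title: Network Pharmacology of Essential-Oil Ingredient-Target-Pathway Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A network-pharmacology pipeline for multi-component medicines
    such as essential oils. Screens chemical ingredients for drug-likeness
    (Lipinski rule of five), filters compound-target interactions by target
    support, tests pathway over-representation with the hypergeometric tail,
    builds an ingredient-target-pathway tripartite network, extracts the
    key-pathway core subnetwork, projects a pathway-based protein
    association network, and computes the graph statistics used to rank
    main active ingredients and key proteins: degree distribution and
    power-law fit, average path length, diameter, clustering coefficient,
    and degree, betweenness and closeness centrality. Includes a
    synthetic-data module that emulates the statistical structure of such
    datasets (hub ingredients, dominant pathways, heavy-tailed
    connectivity) and rebuilds graphs from printed degree tables via the
    configuration model, plus readers and writers for delimited tables,
    GMT gene sets and Pajek .net/.clu files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
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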