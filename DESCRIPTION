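Package: senet
Title: Statistical Epistasis Networks and Dyadicity Analysis of Gene Categories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers statistical epistasis networks from case-control SNP
    genotype data by scoring all SNP pairs with the information gain
    IG(A;B;C) = I(A,B;C) - I(A;C) - I(B;C), thresholding pair scores with a
    permutation-calibrated grid search on global network topology, and
    collapsing the SNP-level network to a gene-gene interaction network.
    Binary gene-category annotations (e.g. Gene Ontology memberships) are
    then characterized on the network by dyadicity and heterophilicity with
    label-shuffling permutation significance. Includes synthetic-data
    generators for genotypes with planted two-locus epistasis and for
    attributed networks with planted dyadic or heterophilic label structure,
    so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
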