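Package: hetrank
Title: Network-Informed Gene Ranking for Heterogeneous Monogenic Disease Exome Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks candidate disease genes in exome-sequencing studies of
    genetically heterogeneous monogenic disease. Variant annotations are turned
    into reciprocal-rank scores per exome, penalized against healthy control
    exomes, shared across a protein interaction network through d-neighborhoods
    gated by an exact hypergeometric chance probability, and summed across
    affected individuals into a final gene ranking. Also provides the
    intersection-filtering baseline ranker, a permutation analysis of disease
    subnetworks under plain and degree-constrained network nulls, and a spike-in
    simulator of exome studies for benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
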