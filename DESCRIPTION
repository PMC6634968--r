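Package: idrsig
Title: Evolutionary Signatures of Intrinsically Disordered Regions
Version: 0.1.0
Authors@R:
    person("idrsig", "developers", email = "idrsig@example.org", role = c("aut", "cre"))
Description: Detects natural selection on molecular features of intrinsically
    disordered protein regions (IDRs) by comparing feature values computed on
    orthologous IDR sets against a simulated phylogenetic null. Provides a
    disorder-specific sequence evolution simulator with power-law indels and
    conserved-segment protection, a catalog of 82 molecular features (charge,
    patterning, composition, complexity, motifs, repeats), empirical p-value
    and Z-score evolutionary signatures, hierarchical clustering of signatures
    with uncentered correlation distance, permutation-based annotation
    enrichment, and a synthetic-data generator so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
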