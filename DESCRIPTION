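Package: procophy
Title: Procrustean Co-Phylogeny Testing with Partial-Sequence Haplogroups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing host-parasite co-diversification from genetic
    distances. Clusters variable-length marker sequences (e.g. microsporidian
    SSU rDNA fragments) into haplogroups by diagnostic sites with explicit
    handling of ambiguous short fragments, computes Tamura-Nei (TN93) pairwise
    distances under pairwise deletion, and runs a Procrustean co-phylogeny
    test: principal coordinates of both distance matrices, link-expanded
    Procrustes superimposition, a global goodness-of-fit statistic with a
    permutation null, jackknife per-link squared residuals with upper 95%
    confidence bounds, and conservative enumeration of alternative association
    matrices arising from ambiguous haplogroup assignments. A synthetic
    co-diversification simulator (Yule host tree, tip prune-and-regraft host
    shifts, TN93 sequence evolution, fragment truncation) provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    seqinr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
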