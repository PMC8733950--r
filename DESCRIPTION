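Package: cladediv
Title: Divergence Testing Between Paralogous Clades of a Gene Tree
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical comparison of the internal divergence of two
    paralogous clades in a rooted gene tree. Given a Newick tree with
    branch lengths and two user-selected clades descending from a gene
    duplication node, the package restricts both clades to their common
    species (identified by a regular-expression pattern on leaf labels),
    selects the least-diverged representative leaf per species, prunes
    each clade with branch-length preservation, and compares the two
    within-clade branch-length samples with Student's t, Welch's t and
    exact/approximate Mann-Whitney U tests. Species-set (Venn/superset)
    analysis, a JSON report, a synthetic duplicated-gene-tree simulator
    and a type-I-error/power harness are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
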