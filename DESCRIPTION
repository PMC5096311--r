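Package: gosimtab
Title: Fast Gene Ontology Semantic Similarity from Precomputed Lookup Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures semantic similarity between Gene Ontology (GO) terms and
    functional similarity between genes using a two-step strategy: first compile
    the ontology graph and an annotation corpus into per-method lookup tables
    (information content, longest-path depth, Wang S-value maps, ancestor sets
    and gene annotation closures), then answer term-term and gene-gene queries
    from those tables alone, without re-traversing the graph. Seven measures are
    provided (Resnik, Lin, Jiang-Conrath, Pekar-Staab, Wang, simUI and simGIC)
    together with the max, average and best-match-average gene-level combination
    rules. Includes OBO 1.2/1.4 and GAF 2.x readers, a synthetic ontology and
    annotation generator, naive repeated-traversal reference implementations
    used to certify that the table-backed fast path is exact, and a command-line
    front end for batch similarity runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
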