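Package: metamapr
Title: Queue-Based Cross-Mapping of Small-Compound Identifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Completes a sparse table of metabolite identifiers across five
    small-compound databases (HMDB, ChEBI, KEGG, PubChem, LIPID MAPS) with a
    queue-based transitive resolution algorithm. A local store of compound
    records acts as a cache: it is bulk-loaded from HMDB XML, ChEBI flat-table
    and LIPID MAPS SDF dumps, while KEGG and PubChem records are fetched per
    identifier through a pluggable transport and cached through. The package
    reports mapping-rate metrics, flags ambiguous (one-to-many) mappings,
    tracks unresolved and retired identifiers, assesses database quality by
    repeated random sampling, and ships a synthetic five-database universe
    generator with controlled cross-reference topology for fully offline
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
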