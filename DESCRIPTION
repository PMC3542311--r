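Package: ucscdb
Title: Offline Access Toolkit for UCSC-Style Genome Annotation Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Query genome annotation stored in UCSC-style relational tables
    without writing SQL. Provides a genomic-interval value type that absorbs
    the difference between browser 1-based closed coordinates and the 0-based
    half-open database convention, the hierarchical bin index used to
    accelerate interval queries on large tables, a pure-R reader and writer
    for the 2bit packed genome sequence format with N-block and soft-mask
    handling, lazy schema reflection with a chainable deferred query builder,
    exon/CDS/intron derivation from genePred gene models, joiner-schema-driven
    table association, and a deterministic synthetic fixture generator so the
    whole stack is testable with no network access.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    DBI,
    RSQLite,
    methods,
    stats,
    tools,
    utils,
    withr
Suggests:
    IRanges,
    RMariaDB,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
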