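# ucscdb

Programmatic, SQL-free access to genome annotation stored in UCSC-style
relational tables, for R users who would otherwise hand-write queries
against `chrom`/`chromStart`/`chromEnd` schemas. The package bundles the
pieces that make such databases usable as a coherent whole:

* **Genomic intervals** — a value type with an explicit coordinate
  contract. Internally everything is 0-based half-open (the database
  storage convention); browser-style 1-based closed strings such as
  `"chr1:123,456-456,789"` are converted at the parse/format boundary, so
  `parse_interval()` maps a printed start *s* to internal *s − 1*.
* **Hierarchical bin index** — the standard five-level scheme (bins of
  512 Mb, 64 Mb, 8 Mb, 1 Mb and 128 kb; level *k* holds 8^k bins starting
  at offsets 0, 1, 9, 73, 585). A feature `[start, end)` is stored in the
  smallest bin that encloses it, found by comparing `start >> shift` with
  `(end − 1) >> shift` from the finest level (shift 17) upward in steps
  of 3. A range query touches only the bins whose extent intersects the
  window (`bins_overlapping()`), which turns a full-table scan into a
  short `bin IN (...)` lookup on large tables.
* **2bit sequence archives** — a pure-R reader *and* writer for the packed
  genome format (4 bases/byte, T=0 C=1 A=2 G=3, with N-block and
  soft-mask block lists), with subsequence extraction that honours both.
* **Lazy ORM layer** — `connect()` / `table_handle()` reflect table
  schemas on first use; `find_by()`/`find_all_by()` and a chainable,
  deferred query builder (`with_interval`, `select`, `where`, `order_by`,
  `limit`, `group`) assemble exactly one parameterized SQL statement per
  terminal call. Interval filters add the bin clause automatically when
  the table has a `bin` column — provably without changing the result set.
* **genePred gene models** — `exons()`, `cdss()` and `introns()` derive
  interval lists from transcript records, ordered along the gene strand.
* **Joiner schemas** — parse `all.joiner`-style link definitions, overwrite
  variables to re-scope the database search, and navigate the resulting
  table associations (or declare them manually with foreign keys).
* **Deterministic fixtures** — generators for conforming SNP tables,
  genePred tables, 2bit genomes with plain-text truth files, and linked
  table pairs, so the entire stack runs and is tested fully offline.

## Worked example

```r
library(ucscdb)

iv <- parse_interval("chr1:123,456-456,789")
iv
#> GenomicInterval chr1 [123455, 456789) width=333334
bin_from_interval(iv$start, iv$end)
#> [1] 73
bins_overlapping(iv$start, iv$end)
#> [1]   0   1   9  73 585 586 587 588

db   <- fixture_db(name = "hg19")
spec <- fixture_spec(seed = 42, feature_count = 500)
fx   <- make_association_fixture(db, spec)   # snpToy + xrefToy + joiner text
snp  <- table_handle(db, "snpToy")
snp
#> <ucsc_table 'hg19'.snpToy: 6 columns, bin-indexed, positional (chrom,chromStart,chromEnd)>

win <- parse_interval("chr1:100,001-400,000")
head(fetch_all(select(with_interval(snp, win), "name", "chromStart", "chromEnd")), 3)
#>   name chromStart chromEnd
#> 1 rs13     144480   148942
#> 2 rs28     383988   387317
#> 3 rs64     108003   109195
count_rows(with_interval_excl(snp, win))   # fully contained features only
#> [1] 9

assoc <- define_association(load_joiner(fx$joiner_text), snp, list(db))[[1]]
assoc
#> <association snpToy.name -> xrefToy.snpId (many) via 'snpName'>
linked_records(assoc, fetch_first(with_interval(snp, win)))
#>   snpId gene
#> 1  rs81 g320
```

The interval string is parsed into the internal 0-based convention
(123,456 → 123455); the 333 kb window straddles a 1 Mb bin boundary, so
its smallest enclosing bin sits one level above the 128 kb bins and a
query for it needs to inspect only 8 of the 4681 possible bins. The
fixture's `snpToy` table is reflected on first use, interval queries run
through the bin clause, and the joiner stanza links each SNP name to its
cross-reference rows.

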