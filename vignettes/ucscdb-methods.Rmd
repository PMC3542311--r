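---
title: "Interval indexing, packed sequences and schema reflection in ucscdb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval indexing, packed sequences and schema reflection in ucscdb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ucscdb)
```

# Scope and model

ucscdb gives R users structured access to genome annotation kept in
UCSC-style relational tables, plus the auxiliary flat files such databases
rely on. Four independent pieces of machinery carry the package, and this
vignette records how each is modelled, which knobs matter, and where the
design was genuinely open.

# Coordinate conventions

Annotation tables store positions 0-based half-open (`chromStart`
inclusive, `chromEnd` exclusive), while browser interfaces print 1-based
fully-closed strings. `GenomicInterval` commits to the storage convention
internally — it is the one the bin arithmetic and SQL comparisons need —
and confines the display convention to `parse_interval()` /
`format_interval()`. A printed start *s* becomes internal *s − 1*; the
printed end is already the exclusive bound. Thousands separators are
accepted on input and never emitted. Two deliberate restrictions:

* Chromosome names are opaque strings. No `"chr"` prefix normalization is
  attempted, because silently mapping `"1"` to `"chr1"` invites
  cross-assembly mistakes the user cannot see.
* Strand is not part of an interval. Positional queries in these schemas
  are strand-agnostic; strand ordering belongs to the gene-model
  accessors.

Empty intervals are rejected at construction. A bare chromosome name is
accepted as a query only when the caller supplies the chromosome length,
since the string itself does not carry one.

# The bin hierarchy

Features are indexed by a five-level hierarchy of bins spanning 512 Mb,
64 Mb, 8 Mb, 1 Mb and 128 kb — exact powers of two (2^29 … 2^17), each
level 8× finer, with level offsets 0, 1, 9, 73, 585 (`offset[k] =
offset[k−1] + 8^(k−1)`). `bin_from_interval()` walks from the finest
level upward, returning `offset + (start >> shift)` at the first level
where `start` and `end − 1` fall in the same bin; `bins_overlapping()`
collects, per level, every bin index between the two shifted endpoints.

The load-bearing property is *soundness*: any stored feature overlapping
a query window has its assigned bin in the window's candidate list, so a
`bin IN (...)` clause conjoined with the positional predicates filters
rows without ever changing the result set. The suite asserts this both
directly (against an oracle that enumerates all 4681 bin extents
explicitly) and end-to-end (interval queries with and without the bin
clause must return identical row sets).

Coordinates at or beyond 2^29 raise an error rather than extending the
scheme: the five-level layout is the one the supported table families
use, and silently switching to an extended layout would produce bin
numbers incompatible with existing `bin` columns.

# 2bit archives

The reader and writer implement the version-0 format: a 16-byte header
(signature `0x1A412743`, version, sequence count, reserved), a name/offset
index, and per-sequence records holding the DNA size, N-block and
mask-block run lists, and DNA packed 4 bases/byte with the first base in
the two highest-order bits (T=0, C=1, A=2, G=3). Decisions worth
recording:

* **Byte order.** The writer always emits little-endian, matching files
  produced by common tooling; the reader detects either order from the
  signature. The writer's big-endian switch is intentionally
  undocumented-in-usage and exists so the reader's detection path is
  exercised by generated fixtures rather than trusted.
* **Bases under N blocks** are stored as code 0. Readers must substitute
  `N` from the block list, so the choice is unobservable; round-trip
  tests assert exactly that.
* **Masking.** `twobit_subseq()` applies N blocks first, then lowercases
  mask-covered positions when `masked = TRUE` (the default, since these
  archives conventionally carry repeat soft-masking); an N inside a mask
  block therefore reads `n`.
* **Laziness.** The header and index parse eagerly; each sequence record
  parses on first access and is cached, mirroring the reflection layer.
* Truncated or corrupt files fail with an error naming the structure
  being read (header, index, block lists, packed DNA), which in practice
  distinguishes a short download from a wrong file.

The long (64-bit offset) format variant and `.nib` files are out of scope.

# Reflection and the query builder

`connect()` opens a handle without touching any table; `table_handle()`
reflects the column metadata once per handle and caches it. Reflection
detects two structural facts: whether a `bin` column exists, and which
positional triple the table carries — `(chrom, chromStart, chromEnd)`
preferred, then genePred's `(chrom, txStart, txEnd)`, then PSL-style
`(tName, tStart, tEnd)`. That fallback list covers the common table
families without per-table configuration; a table matching none of them
simply refuses interval queries.

Query expressions are immutable: every clause returns a new expression,
and only the terminals (`fetch_all`, `fetch_first`, `count_rows`) issue a
backend query — exactly one, assembled from all accumulated clauses.
Filters conjoin with AND only; an OR surface was deliberately omitted to
keep generated SQL predictable. All values travel as bound parameters;
identifiers are validated against the reflected column list before
execution, so an unknown column fails fast and client-side.

Two smaller choices:

* **Deterministic "first".** Row order for `fetch_first()`/`find_by()` is
  otherwise backend-dependent, so terminals append a tiebreak ordering on
  the primary key (or the first reflected column when there is none,
  as in the key-less UCSC dump schemas). Repeated identical queries
  therefore return identically ordered results.
* **Read-only surface.** The query layer performs no writes against
  annotation databases; fixture creation goes through a separate
  `fixture_db()` constructor that is allowed to create files, keeping
  `connect()`'s must-exist contract strict.

The MySQL server dialect is supported at the URI level (`mysql://…`) and
requires the optional RMariaDB driver; all tests and examples run against
embedded SQLite databases, so no network or server is ever needed.

# genePred accessors

`exons()`, `cdss()` and `introns()` derive interval lists from a
validated gene-model record. Validation is strict: exon lists must be
equal-length, sorted, non-overlapping and inside the transcript span, and
the CDS must nest in the transcript (`cdsStart == cdsEnd` encodes
non-coding). Records violating the invariants are rejected loudly rather
than repaired — a disagreeing dump row is more likely a parsing or
versioning problem than something a library should silently fix.

CDS intervals are the per-exon intersections with `[cdsStart, cdsEnd)`,
dropping empty pieces; introns are the inter-exon gaps, with zero-length
gaps (abutting exons) omitted. "Sorted by strand" means list order only:
on the minus strand the lists reverse (gene 5′→3′) while each interval
keeps `start < end`. Comma-blob parsing tolerates the single trailing
comma of standard dumps. Codon phase and UTR accessors are out of scope.

# Joiner schemas

The parser supports the grammar that association definition actually
needs: comments, `set name value`, `identifier` stanza headers with an
optional quoted description, and indented `db.table.field` member lines.
Anything after the member reference is retained as inert option tokens —
the exceptional directives (field transformations, chromosome-split
tables) carry no semantics here and members must have exactly the three
components. Two behaviours are worth making explicit:

* **Late substitution.** `$var` references expand when associations are
  defined, not at load time, so overwriting a variable that holds a
  comma-separated database list (conventionally `gbd`) re-scopes which
  databases the link search considers; a member whose database component
  expands to a list fans out to one member per database.
* **Skip, don't fail.** Members on unconnected databases or missing
  tables are silently skipped — that is the contract that makes a global
  schema usable against a partial mirror. The same treatment is extended
  to members whose *field* is absent from an existing table, a case the
  contract leaves open; erroring there would make one stale stanza poison
  an otherwise valid schema.
* When two stanzas link the same field pair, both associations are kept
  and navigation deduplicates result rows; with no stated conflict rule,
  deduplication is the conservative reading.

Navigation always returns a data.frame — possibly 0-row, one row for
`has_one`-style associations (the deterministic first) — never a scalar
or `NULL`, so downstream code needs no case analysis.

# Synthetic fixtures: what they emulate and what they do not

The generators produce schema-conforming content, deterministically from
a seed (per-generator sub-seeds keep outputs independent of call order):

* SNP-style tables: features uniform over a two-chromosome toy genome
  (defaults 5 Mb + 3 Mb — large enough to spread rows over many 128 kb
  bins and across bin levels), lengths uniform on 1–10,000 bp, `bin`
  computed from the span.
* genePred tables: 1–20 exons (50–300 bp, gaps 30–2000 bp), CDS bounds
  uniform within the transcript, ~10% non-coding, strands balanced.
* 2bit genomes: uniform ACGT with 0–3 planted N runs and soft-mask runs
  per sequence, paired with a FASTA truth file.
* Association fixtures: a configurable fraction of SNP names referenced
  by a cross-reference table (1–2 rows each), plus dangling references,
  with the expected equijoin computed by brute force.

These exercise every structural contract (schemas, conventions, block
lists, key overlap) but none of the *content* statistics of real
annotation — no clustering of SNPs, no realistic exon length or GC
distributions, no tens-of-millions-row tables. Passing tests therefore
demonstrate correctness of the access machinery, not performance at
dbSNP scale, and say nothing about any particular organism's data.

# Validation sizes and numerical notes

The suite and the acceptance script validate at these sizes, chosen to
exhaust the combinatorics they probe while keeping a laptop run in
seconds: 10,000 random intervals against the explicit bin-extent oracle
(widths up to 8 Mb, spanning all five levels); 500 features × 50 windows
for interval-query equivalence (IRanges serves as the independent overlap
oracle in the suite; the acceptance script uses a direct predicate scan);
1000 random sequences (1–5000 bp) for the 2bit round trip; 1000 intervals
for the string round trip; 200 gene models for the partition property.

All coordinates are handled as doubles (exact for whole numbers far
beyond 2^29), with shift arithmetic expressed as division by powers of
two; archive integers are decoded unsigned via a 2^32 correction.

# Known limitations

BigWig/BigBed/BAM-backed tables, the extended (>512 Mb) bin scheme, the
64-bit 2bit variant, OR/NOT query composition, cross-server federated
joins and semantic handling of exceptional joiner directives are all out
of scope. The MySQL path is surface-supported but unexercised by the
offline suite.
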