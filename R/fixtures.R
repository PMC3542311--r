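# Deterministic synthetic-data generators. Everything is reproducible from
# the FixtureSpec seed alone (per-generator sub-seeds keep the outputs
# independent of call order), so every module is testable offline.

#' Fixture specification
#'
#' Bundles the knobs of the synthetic-data generators: the seed, the
#' chromosome sizes of the toy genome, how many features each table gets,
#' and — for association fixtures — the fraction of key values shared
#' between the two tables. The same spec always regenerates byte-identical
#' content.
#'
#' @param seed Integer seed.
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp
#'   (each at most 2^29). The defaults give a two-chromosome toy genome
#'   large enough to spread features over many 128kb bins.
#' @param feature_count Rows per generated table.
#' @param key_overlap Fraction in `[0, 1]` of annotation keys that the
#'   cross-reference table points at.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         chrom_sizes = c(chr1 = 5e6, chr2 = 3e6),
                         feature_count = 500L,
                         key_overlap = 0.5) {
  if (!is_whole(seed)) stop_user("seed must be a whole number")
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    stop_user("chrom_sizes must be a named vector")
  }
  if (any(chrom_sizes > 2^29)) {
    stop_user("chromosome length %s exceeds 2^29, the bin scheme's range",
              format(max(chrom_sizes), scientific = FALSE))
  }
  if (any(chrom_sizes < 1)) stop_user("chromosome lengths must be positive")
  if (!is_whole(feature_count) || feature_count < 0) {
    stop_user("feature_count must be a non-negative whole number")
  }
  if (!is.numeric(key_overlap) || key_overlap < 0 || key_overlap > 1) {
    stop_user("key_overlap must be in [0, 1]")
  }
  structure(list(seed = as.integer(seed), chrom_sizes = chrom_sizes,
                 feature_count = as.integer(feature_count),
                 key_overlap = key_overlap),
            class = "fixture_spec")
}

.sub_seed <- function(spec, offset) {
  as.integer((abs(spec$seed) + offset) %% (.Machine$integer.max - 1L))
}

#' Open (or create) a writable fixture database
#'
#' Unlike [connect()], which targets existing annotation databases, this
#' opens an embedded SQLite database that may not exist yet, for the
#' fixture generators to populate. The returned handle is a regular
#' `ucsc_db` usable with the whole query surface.
#'
#' @param path SQLite file path, or `":memory:"` (the default).
#' @param name Database label (used by joiner association lookup).
#' @return A `ucsc_db` handle.
#' @export
fixture_db <- function(path = ":memory:", name = NULL) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  default_name <- if (path == ":memory:") "memory" else {
    tools::file_path_sans_ext(basename(path))
  }
  new_db_handle(con, path, name %||% default_name)
}

#' Generate a snp-style annotation table
#'
#' Populates `table_name` with the classic positional schema
#' (bin, chrom, chromStart, chromEnd, name, strand): features are placed
#' uniformly over the spec's chromosomes with lengths uniform in 1–10000 bp
#' (clipped to the chromosome), names `rs1, rs2, ...`, random strand, and
#' the `bin` column computed with [bin_from_interval()].
#'
#' @param db A writable [fixture_db()] handle.
#' @param spec A [fixture_spec()].
#' @param table_name Table to (over)write.
#' @return The generated rows, invisibly.
#' @export
make_snp_table <- function(db, spec, table_name = "snpToy") {
  stopifnot(inherits(db, "ucsc_db"), inherits(spec, "fixture_spec"))
  n <- spec$feature_count
  cs <- spec$chrom_sizes
  df <- withr::with_seed(.sub_seed(spec, 101L), {
    chrom <- sample(names(cs), n, replace = TRUE)
    len <- pmin(sample.int(10000L, n, replace = TRUE), cs[chrom])
    start <- floor(stats::runif(n, 0, cs[chrom] - len + 1))
    start <- pmin(start, cs[chrom] - len)  # guard the open upper bound
    end <- start + len
    data.frame(bin = if (n) mapply(bin_from_interval, start, end) else integer(),
               chrom = chrom,
               chromStart = as.integer(start),
               chromEnd = as.integer(end),
               name = if (n) paste0("rs", seq_len(n)) else character(),
               strand = sample(c("+", "-"), n, replace = TRUE),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  DBI::dbWriteTable(db$con, table_name, df, overwrite = TRUE)
  invisible(df)
}

#' Generate a genePred gene-model table
#'
#' Populates `table_name` with random valid gene models: 1–20 exons per
#' gene (sorted, disjoint, inside the transcript span), CDS nested in the
#' transcript, about 10% non-coding transcripts (cdsStart == cdsEnd), both
#' strands equally likely, exon lists serialized as comma-separated blobs
#' with the conventional trailing comma, plus a `bin` column over the
#' transcript span. Every row satisfies the genePred invariants by
#' construction.
#'
#' @inheritParams make_snp_table
#' @return The generated rows (exon lists as text blobs), invisibly.
#' @export
make_genepred_table <- function(db, spec, table_name = "refGeneToy") {
  stopifnot(inherits(db, "ucsc_db"), inherits(spec, "fixture_spec"))
  n <- spec$feature_count
  cs <- spec$chrom_sizes
  rows <- withr::with_seed(.sub_seed(spec, 102L), {
    lapply(seq_len(n), function(i) {
      chrom <- sample(names(cs), 1L)
      L <- cs[[chrom]]
      k <- sample.int(20L, 1L)
      exon_len <- sample(50:300, k, replace = TRUE)
      gap_len <- if (k > 1L) sample(30:2000, k - 1L, replace = TRUE) else integer()
      span <- sum(exon_len) + sum(gap_len)
      if (span >= L) stop_user("chromosome '%s' too short for a gene model", chrom)
      tx_start <- sample.int(L - span, 1L) - 1L
      starts <- tx_start + cumsum(c(0L, exon_len[-k] + gap_len))
      ends <- starts + exon_len
      tx_end <- ends[k]
      if (stats::runif(1) < 0.1) {
        cds_start <- cds_end <- tx_start
      } else {
        b <- sort(sample(tx_start:tx_end, 2L))
        while (b[1L] == b[2L]) b <- sort(sample(tx_start:tx_end, 2L))
        cds_start <- b[1L]
        cds_end <- b[2L]
      }
      list(bin = bin_from_interval(tx_start, tx_end),
           name = paste0("tx", i), chrom = chrom,
           strand = sample(c("+", "-"), 1L),
           txStart = tx_start, txEnd = tx_end,
           cdsStart = cds_start, cdsEnd = cds_end,
           exonCount = k,
           exonStarts = paste0(paste(starts, collapse = ","), ","),
           exonEnds = paste0(paste(ends, collapse = ","), ","))
    })
  })
  df <- if (n) {
    do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  } else {
    data.frame(bin = integer(), name = character(), chrom = character(),
               strand = character(), txStart = integer(), txEnd = integer(),
               cdsStart = integer(), cdsEnd = integer(), exonCount = integer(),
               exonStarts = character(), exonEnds = character(),
               stringsAsFactors = FALSE)
  }
  row.names(df) <- NULL
  DBI::dbWriteTable(db$con, table_name, df, overwrite = TRUE)
  invisible(df)
}

# Random DNA with N runs and soft-mask runs, as a single string.
.random_dna <- function(len) {
  x <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  plant_runs <- function(x, n_runs, max_len, fn) {
    for (i in seq_len(n_runs)) {
      rl <- sample.int(min(max_len, len), 1L)
      rs <- sample.int(len - rl + 1L, 1L)
      x[rs:(rs + rl - 1L)] <- fn(x[rs:(rs + rl - 1L)])
    }
    x
  }
  x <- plant_runs(x, sample(0:3, 1L), 200L, function(v) rep("N", length(v)))
  x <- plant_runs(x, sample(0:3, 1L), 500L, tolower)
  paste(x, collapse = "")
}

#' Generate a toy genome 2bit archive with a plain-text truth file
#'
#' Writes one random sequence per chromosome of the spec (uniform ACGT with
#' a few random N runs and soft-masked lowercase runs) as a 2bit archive,
#' together with a FASTA truth file holding the exact strings for oracle
#' comparison.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @param basename Stem for the two output files.
#' @return Invisibly, a list with `archive` (2bit path), `truth_path`
#'   (FASTA path) and `truth` (named character vector of the sequences).
#' @export
make_genome_2bit <- function(spec, dir, basename = "genome") {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- withr::with_seed(.sub_seed(spec, 103L), {
    vapply(spec$chrom_sizes, .random_dna, "")
  })
  names(seqs) <- names(spec$chrom_sizes)
  archive <- file.path(dir, paste0(basename, ".2bit"))
  twobit_write(archive, seqs)
  truth_path <- file.path(dir, paste0(basename, "_truth.fa"))
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), truth_path)
  invisible(list(archive = archive, truth_path = truth_path, truth = seqs))
}

#' Generate an association fixture: two linked tables plus joiner text
#'
#' Builds a snp-style table and a cross-reference table whose `snpId`
#' column points at a `key_overlap` fraction of the snp names (1–2 rows per
#' matched name, plus some deliberately dangling references), emits the
#' matching joiner stanza text, and computes the expected equijoin by brute
#' force for oracle comparison.
#'
#' @inheritParams make_snp_table
#' @param snp_table,xref_table Names for the two tables.
#' @return Invisibly, a list with the generated `snp` and `xref` rows, the
#'   `joiner_text`, and `expected` (the brute-force join of the two tables
#'   on name == snpId).
#' @export
make_association_fixture <- function(db, spec, snp_table = "snpToy",
                                     xref_table = "xrefToy") {
  snp <- make_snp_table(db, spec, snp_table)
  n <- nrow(snp)
  xref <- withr::with_seed(.sub_seed(spec, 104L), {
    n_match <- round(spec$key_overlap * n)
    matched <- if (n_match > 0) sample(snp$name, n_match) else character()
    reps <- if (n_match > 0) sample(1:2, n_match, replace = TRUE) else integer()
    ids <- c(rep(matched, reps), sprintf("nohit%d", seq_len(max(3L, round(0.1 * n)))))
    data.frame(snpId = ids,
               gene = paste0("g", seq_along(ids)),
               stringsAsFactors = FALSE)
  })
  DBI::dbWriteTable(db$con, xref_table, xref, overwrite = TRUE)
  joiner_text <- sprintf("set db %s\nidentifier snpName\n  $db.%s.name\n  $db.%s.snpId\n",
                         db$name, snp_table, xref_table)
  expected <- merge(snp, xref, by.x = "name", by.y = "snpId")
  invisible(list(snp = snp, xref = xref, joiner_text = joiner_text,
                 expected = expected))
}
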