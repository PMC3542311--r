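local_snp_db <- function(seed = 7, n = 200, env = parent.frame()) {
  db <- fixture_db()
  withr::defer(disconnect(db), envir = env)
  spec <- fixture_spec(seed = seed, feature_count = n)
  rows <- make_snp_table(db, spec)
  list(db = db, rows = rows, spec = spec)
}

test_that("connect validates locators and keeps handles independent", {
  expect_error(connect("bogus://x"), "unsupported connection scheme",
               class = "ucscdb_user_error")
  expect_error(connect(file.path(tempdir(), "no-such.sqlite")), "does not exist",
               class = "ucscdb_user_error")

  a <- local_snp_db(seed = 1, n = 30)
  b <- local_snp_db(seed = 2, n = 55)
  expect_length(ls(a$db$tables), 0L)  # nothing reflected until first table use
  expect_equal(count_rows(table_handle(a$db, "snpToy")), 30)
  expect_equal(count_rows(table_handle(b$db, "snpToy")), 55)
})

test_that("schema reflection happens once per handle and detects bin/positional columns", {
  fx <- local_snp_db()
  db <- fx$db
  DBI::dbWriteTable(db$con, "noBinToy",
                    data.frame(chrom = "chr1", chromStart = 1L, chromEnd = 5L,
                               name = "x"))
  t1 <- table_handle(db, "snpToy")
  expect_true(t1$has_bin)
  expect_equal(t1$positional, c("chrom", "chromStart", "chromEnd"))
  n_reflect <- db$reflect_count
  t2 <- table_handle(db, "snpToy")
  expect_identical(db$reflect_count, n_reflect)  # cached: no second schema read
  t3 <- table_handle(db, "noBinToy")
  expect_false(t3$has_bin)
  expect_equal(db$reflect_count, n_reflect + 1L)
  expect_error(table_handle(db, "missing"), "available.*noBinToy",
               class = "ucscdb_user_error")
})

test_that("find_by / find_all_by match an in-memory filter", {
  fx <- local_snp_db(seed = 9, n = 500)
  t <- table_handle(fx$db, "snpToy")
  DBI::dbWriteTable(fx$db$con, "dupToy",
                    data.frame(name = c("rs1", "rs2", "rs2"), v = 1:3))
  td <- table_handle(fx$db, "dupToy")
  expect_equal(nrow(find_all_by(td, "name", "rs2")), 2L)
  expect_null(find_by(td, "name", "absent"))
  expect_error(find_by(t, "nonesuch", 1), "unknown field", class = "ucscdb_user_error")

  for (val in c("+", "-")) {
    expect_same_rows(find_all_by(t, "strand", val),
                     fx$rows[fx$rows$strand == val, ])
  }
  for (nm in sample(fx$rows$name, 20)) {
    expect_same_rows(find_all_by(t, "name", nm), fx$rows[fx$rows$name == nm, ])
  }
})

test_that("record field access is strict", {
  fx <- local_snp_db()
  r <- find_by(table_handle(fx$db, "snpToy"), "name", "rs1")
  expect_s3_class(r, "ucsc_record")
  expect_type(r$chromStart, "integer")  # storage types preserved
  expect_error(r$no_such_field, "no field", class = "ucscdb_user_error")
  expect_error(r[["no_such_field"]], "no field", class = "ucscdb_user_error")
})

test_that("interval queries equal an IRanges scan, with and without the bin clause", {
  skip_if_not_installed("IRanges")
  fx <- local_snp_db(seed = 41, n = 500)
  t <- table_handle(fx$db, "snpToy")
  withr::with_seed(42, {
    for (i in 1:25) {
      chrom <- sample(names(fx$spec$chrom_sizes), 1L)
      w <- sample.int(300000L, 1L)
      s <- floor(runif(1, 0, fx$spec$chrom_sizes[[chrom]] - w))
      iv <- GenomicInterval(chrom, s, s + w)
      want_ov <- iranges_overlap_scan(fx$rows, iv)
      want_in <- iranges_within_scan(fx$rows, iv)
      got_ov <- fetch_all(with_interval(t, iv))
      expect_same_rows(got_ov, want_ov)
      expect_same_rows(fetch_all(with_interval(t, iv, use_bin = FALSE)), want_ov)
      got_in <- fetch_all(with_interval_excl(t, iv))
      expect_same_rows(got_in, want_in)
      expect_same_rows(fetch_all(with_interval_excl(t, iv, use_bin = FALSE)), want_in)
      expect_true(all(got_in$name %in% got_ov$name))  # containment is a subset
    }
  })
})

test_that("interval edge semantics: abutment excluded, equality contained, beyond-range empty", {
  db <- fixture_db()
  withr::defer(disconnect(db))
  DBI::dbWriteTable(db$con, "edgeToy",
                    data.frame(bin = vapply(list(c(100L, 200L), c(200L, 300L)),
                                            function(p) bin_from_interval(p[1], p[2]), 0L),
                               chrom = "chr1",
                               chromStart = c(100L, 200L), chromEnd = c(200L, 300L),
                               name = c("left", "right")))
  t <- table_handle(db, "edgeToy")
  win <- GenomicInterval("chr1", 200, 300)
  got <- fetch_all(with_interval(t, win))
  expect_equal(got$name, "right")            # feature.end == window.start excluded
  expect_equal(fetch_all(with_interval_excl(t, win))$name, "right")  # equal to window: included
  expect_equal(nrow(fetch_all(with_interval(t, GenomicInterval("chr1", 5000, 6000)))), 0L)
  DBI::dbWriteTable(db$con, "plainToy", data.frame(k = 1:3))
  expect_error(with_interval(table_handle(db, "plainToy"), win),
               "positional", class = "ucscdb_user_error")
})

test_that("clauses chain lazily and terminals issue exactly one query", {
  fx <- local_snp_db(seed = 5, n = 300)
  db <- fx$db
  t <- table_handle(db, "snpToy")
  before <- db$query_count
  q <- limit(order_by(where(select(with_interval(t, GenomicInterval("chr1", 0, 2^22)),
                                   "name", "chromStart"),
                            "strand = ?", "+"),
                      "chromStart"), 5)
  expect_identical(db$query_count, before)  # building touched the backend zero times
  res <- fetch_all(q)
  expect_identical(db$query_count, before + 1L)
  expect_lte(nrow(res), 5L)
  expect_equal(names(res), c("name", "chromStart"))

  # order_by equals a brute-force sort (tiebreak on the bin column, the
  # deterministic default ordering of this table)
  all_rows <- fetch_all(order_by(t, "chromStart"))
  want <- fx$rows[order(fx$rows$chromStart, fx$rows$bin), ]
  row.names(want) <- NULL
  expect_equal(all_rows, want)

  # where + count equals a brute-force count
  expect_equal(count_rows(where(t, "strand = ?", "+")),
               sum(fx$rows$strand == "+"))
  expect_equal(count_rows(limit(t, 7)), 7L)
})

test_that("identical queries return identically ordered results", {
  fx <- local_snp_db(seed = 13, n = 120)
  t <- table_handle(fx$db, "snpToy")
  q <- where(t, "chromStart > ?", 1000)
  expect_identical(fetch_all(q), fetch_all(q))
})

test_that("values reach the backend as bound parameters, not interpolated text", {
  db <- fixture_db()
  withr::defer(disconnect(db))
  tricky <- "O'Reilly\"; DROP TABLE x; --"
  DBI::dbWriteTable(db$con, "quirk", data.frame(name = c(tricky, "plain"), v = 1:2))
  t <- table_handle(db, "quirk")
  got <- find_all_by(t, "name", tricky)
  expect_equal(nrow(got), 1L)
  expect_identical(got$name, tricky)
  expect_equal(count_rows(where(t, "name = ?", tricky)), 1L)
  expect_error(where(t, "name = ?"), "placeholder", class = "ucscdb_user_error")
})

test_that("unknown columns in any clause fail before execution", {
  fx <- local_snp_db()
  t <- table_handle(fx$db, "snpToy")
  before <- fx$db$query_count
  expect_error(select(t, "nope"), "unknown field", class = "ucscdb_user_error")
  expect_error(order_by(t, "nope"), "unknown field", class = "ucscdb_user_error")
  expect_error(group(t, "nope"), "unknown field", class = "ucscdb_user_error")
  expect_identical(fx$db$query_count, before)
})

test_that("group() aggregates through the backend", {
  fx <- local_snp_db(seed = 3, n = 100)
  t <- table_handle(fx$db, "snpToy")
  got <- fetch_all(group(select(t, "chrom"), "chrom"))
  expect_setequal(got$chrom, unique(fx$rows$chrom))
})
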