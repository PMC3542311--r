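two_exon <- function(strand = "+", cds = c(150, 350)) {
  genepred_record(name = "g1", chrom = "chr1", strand = strand,
                  txStart = 100, txEnd = 400, cdsStart = cds[1], cdsEnd = cds[2],
                  exonStarts = c(100, 300), exonEnds = c(200, 400))
}

iv_pairs <- function(ivs) lapply(ivs, function(iv) c(iv$start, iv$end))

test_that("exons come back in gene order: genomic on +, reversed on -", {
  expect_equal(iv_pairs(exons(two_exon("+"))), list(c(100, 200), c(300, 400)))
  expect_equal(iv_pairs(exons(two_exon("-"))), list(c(300, 400), c(100, 200)))
  expect_equal(exons(two_exon("-"))[[1]]$chrom, "chr1")
})

test_that("cdss intersect each exon with the coding span; non-coding gives an empty list", {
  expect_equal(iv_pairs(cdss(two_exon("+"))), list(c(150, 200), c(300, 350)))
  expect_equal(iv_pairs(cdss(two_exon("-"))), list(c(300, 350), c(150, 200)))
  nc <- genepred_record(chrom = "chr1", strand = "+", txStart = 100, txEnd = 400,
                        cdsStart = 100, cdsEnd = 100,
                        exonStarts = "100,300,", exonEnds = "200,400,")
  expect_equal(cdss(nc), list())
  # base-level check of the worked example
  g <- two_exon("+")
  expect_equal(iv_bases(cdss(g)),
               intersect(iv_bases(exons(g)), 150:349))
})

test_that("introns are the gaps between consecutive exons", {
  expect_equal(iv_pairs(introns(two_exon("+"))), list(c(200, 300)))
  expect_equal(iv_pairs(introns(two_exon("-"))), list(c(200, 300)))
  single <- genepred_record(chrom = "chr1", strand = "+", txStart = 10, txEnd = 50,
                            cdsStart = 10, cdsEnd = 50,
                            exonStarts = 10, exonEnds = 50)
  expect_equal(introns(single), list())
  # abutting exons produce no zero-length intron
  abut <- genepred_record(chrom = "chr1", strand = "+", txStart = 0, txEnd = 20,
                          cdsStart = 0, cdsEnd = 20,
                          exonStarts = c(0, 10), exonEnds = c(10, 20))
  expect_equal(introns(abut), list())
})

test_that("exons and introns tile the transcript span; cds bases nest in exon bases", {
  db <- fixture_db()
  withr::defer(disconnect(db))
  rows <- make_genepred_table(db, fixture_spec(seed = 51, feature_count = 200))
  for (i in seq_len(nrow(rows))) {
    g <- as_genepred(rows[i, ])
    ex <- exons(g)
    expect_equal(sum(vapply(ex, iv_width, 0)),
                 sum(g$exonEnds - g$exonStarts))  # length conservation
    eb <- iv_bases(ex)
    ib <- iv_bases(introns(g))
    expect_length(intersect(eb, ib), 0L)                      # disjoint
    expect_equal(sort(c(eb, ib)), seq(g$txStart, g$txEnd - 1))  # contiguous cover
    cb <- iv_bases(cdss(g))
    expect_equal(cb, intersect(eb, seq(g$cdsStart, length.out = max(0, g$cdsEnd - g$cdsStart))))
    # strand reversal exactly reverses every list
    flipped <- g
    flipped$strand <- if (g$strand == "+") "-" else "+"
    expect_equal(iv_pairs(exons(flipped)), rev(iv_pairs(ex)))
    expect_equal(iv_pairs(introns(flipped)), rev(iv_pairs(introns(g))))
    expect_equal(iv_pairs(cdss(flipped)), rev(iv_pairs(cdss(g))))
  }
})

test_that("invariant violations are rejected loudly, naming the field", {
  expect_error(genepred_record(chrom = "chr1", strand = "+", txStart = 0, txEnd = 100,
                               cdsStart = 0, cdsEnd = 100,
                               exonStarts = c(0, 40), exonEnds = c(50, 100)),
               "exonStarts", class = "ucscdb_user_error")  # overlapping exons
  expect_error(genepred_record(chrom = "chr1", strand = "+", txStart = 10, txEnd = 100,
                               cdsStart = 0, cdsEnd = 100,
                               exonStarts = 10, exonEnds = 100),
               "cdsStart", class = "ucscdb_user_error")  # CDS outside tx
  expect_error(genepred_record(chrom = "chr1", strand = "*", txStart = 0, txEnd = 10,
                               cdsStart = 0, cdsEnd = 10, exonStarts = 0, exonEnds = 10),
               "strand", class = "ucscdb_user_error")
  expect_error(genepred_record(chrom = "chr1", strand = "+", txStart = 0, txEnd = 10,
                               cdsStart = 0, cdsEnd = 10, exonStarts = 0, exonEnds = 10,
                               exonCount = 2),
               "exonCount", class = "ucscdb_user_error")
  expect_error(genepred_record(chrom = "chr1", strand = "+", txStart = 0, txEnd = 100,
                               cdsStart = 0, cdsEnd = 100,
                               exonStarts = "0,x,", exonEnds = "10,100,"),
               "non-integer", class = "ucscdb_user_error")
})

test_that("genePred text dumps read back and feed the accessors", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(paste(c("tx1", "chr7", "-", "1000", "5000", "1200", "4800",
                     "3", "1000,2000,4000,", "1500,2500,5000,"),
                   collapse = "\t"), path)
  df <- read_genepred(path)
  expect_equal(nrow(df), 1L)
  g <- as_genepred(df[1, ])
  expect_equal(g$exonCount, 3L)
  expect_equal(iv_pairs(exons(g))[[1]], c(4000, 5000))  # minus strand: last first
})

test_that("rows fetched through the query layer gain the accessors", {
  db <- fixture_db()
  withr::defer(disconnect(db))
  make_genepred_table(db, fixture_spec(seed = 52, feature_count = 20))
  t <- table_handle(db, "refGeneToy")
  expect_equal(t$positional, c("chrom", "txStart", "txEnd"))
  r <- find_by(t, "name", "tx5")
  g <- as_genepred(r)
  expect_s3_class(g, "genepred")
  expect_gte(length(exons(g)), 1L)
})
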