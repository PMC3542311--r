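# Independent oracles used across the suite. These deliberately avoid the
# implementation's shift arithmetic and SQL paths.

# Every bin at every level with its explicit genomic extent.
bin_extent_table <- local({
  tbl <- NULL
  function() {
    if (is.null(tbl)) {
      sch <- ucscdb::bin_scheme()
      tbl <<- do.call(rbind, lapply(seq_along(sch$level_spans), function(k) {
        span <- sch$level_spans[k]
        n <- sch$max_position / span
        data.frame(bin = sch$level_offsets[k] + seq_len(n) - 1L,
                   start = (seq_len(n) - 1) * span,
                   end = seq_len(n) * span,
                   span = span)
      }))
    }
    tbl
  }
})

# Smallest-span bin fully containing [start, end), by direct enumeration.
oracle_smallest_bin <- function(start, end) {
  bt <- bin_extent_table()
  cand <- bt[bt$start <= start & end <= bt$end, ]
  cand$bin[which.min(cand$span)]
}

# All bins whose extent intersects [start, end), by direct enumeration.
oracle_bins_overlapping <- function(start, end) {
  bt <- bin_extent_table()
  sort(bt$bin[bt$start < end & start < bt$end])
}

# Row-set equality ignoring row order.
expect_same_rows <- function(a, b) {
  canon <- function(df) {
    df <- df[do.call(order, df), , drop = FALSE]
    row.names(df) <- NULL
    df
  }
  expect_equal(canon(as.data.frame(a)), canon(as.data.frame(b)))
}

# IRanges-backed overlap/containment scans over a positional data.frame
# (independent of the package's SQL construction).
iranges_overlap_scan <- function(df, iv) {
  hits <- IRanges::overlapsAny(
    IRanges::IRanges(df$chromStart + 1L, df$chromEnd),
    IRanges::IRanges(iv$start + 1L, iv$end))
  df[df$chrom == iv$chrom & hits, , drop = FALSE]
}

iranges_within_scan <- function(df, iv) {
  hits <- IRanges::overlapsAny(
    IRanges::IRanges(df$chromStart + 1L, df$chromEnd),
    IRanges::IRanges(iv$start + 1L, iv$end), type = "within")
  df[df$chrom == iv$chrom & hits, , drop = FALSE]
}

# 0-based base positions covered by a list of GenomicInterval objects.
iv_bases <- function(ivs) {
  if (!length(ivs)) return(numeric(0))
  sort(unlist(lapply(ivs, function(iv) seq(iv$start, iv$end - 1))))
}

# Random DNA string with planted N runs and soft-mask runs.
random_dna_string <- function(len) {
  x <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  for (i in seq_len(sample(0:3, 1L))) {
    rl <- sample.int(min(50L, len), 1L)
    rs <- sample.int(len - rl + 1L, 1L)
    x[rs:(rs + rl - 1L)] <- "N"
  }
  for (i in seq_len(sample(0:3, 1L))) {
    rl <- sample.int(min(80L, len), 1L)
    rs <- sample.int(len - rl + 1L, 1L)
    x[rs:(rs + rl - 1L)] <- tolower(x[rs:(rs + rl - 1L)])
  }
  paste(x, collapse = "")
}

# Random valid GenomicInterval.
random_interval <- function(max_pos = 2^29) {
  chrom <- sample(c("chr1", "chr2", "chrX", "scaffold_12"), 1L)
  w <- sample.int(10000L, 1L)
  s <- floor(runif(1, 0, max_pos - w))
  ucscdb::GenomicInterval(chrom, s, s + w)
}
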