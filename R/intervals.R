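#' Genomic interval value type
#'
#' A `GenomicInterval` is a chromosome name plus a coordinate span in the
#' 0-based half-open convention used by UCSC-style database tables
#' (`chromStart` inclusive, `chromEnd` exclusive). The browser's 1-based
#' fully-closed convention appears only at the [parse_interval()] /
#' [format_interval()] boundary. Intervals are strand-agnostic; strand
#' ordering lives in the genePred accessors.
#'
#' @param chrom Chromosome name. Opaque non-empty string without whitespace
#'   or colons; no `"chr"`-prefix normalization is attempted.
#' @param start 0-based inclusive start, in base pairs.
#' @param end 0-based exclusive end, in base pairs. Must exceed `start`;
#'   empty intervals are rejected.
#' @return An object of class `GenomicInterval` with fields `chrom`, `start`
#'   and `end`.
#' @examples
#' iv <- GenomicInterval("chr1", 123455, 456789)
#' iv_width(iv)
#' @seealso [parse_interval()], [overlaps()], [contains()]
#' @export
GenomicInterval <- function(chrom, start, end) {
  if (!is_scalar_string(chrom) || !nzchar(chrom)) {
    stop_user("chromosome name must be a non-empty string")
  }
  if (grepl("[[:space:]:]", chrom)) {
    stop_user("chromosome name '%s' contains whitespace or ':'", chrom)
  }
  if (!is_whole(start) || !is_whole(end)) {
    stop_user("interval bounds must be whole numbers")
  }
  if (start < 0) stop_user("interval start must be >= 0 (got %s)", format(start))
  if (start >= end) {
    stop_user("interval start (%s) must be less than end (%s); empty intervals are not allowed",
              format(start), format(end))
  }
  structure(list(chrom = chrom, start = as.numeric(start), end = as.numeric(end)),
            class = "GenomicInterval")
}

#' @rdname GenomicInterval
#' @param iv A `GenomicInterval`.
#' @export
iv_width <- function(iv) {
  stopifnot(inherits(iv, "GenomicInterval"))
  iv$end - iv$start
}

#' @export
print.GenomicInterval <- function(x, ...) {
  cat(sprintf("GenomicInterval %s [%s, %s) width=%s\n",
              x$chrom, format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE),
              format(iv_width(x), scientific = FALSE)))
  invisible(x)
}

#' Parse a browser-style interval string
#'
#' Accepts strings of the form `"chr1:123,456-456,789"` as used by genome
#' browser interfaces: coordinates are 1-based and fully closed, and may
#' contain thousands-separator commas. The result is converted to the
#' internal 0-based half-open convention (`start - 1`, `end`). A bare
#' chromosome name (no `:`) denotes the whole chromosome and is accepted
#' only when `chrom_length` supplies the length.
#'
#' @param text Interval string.
#' @param chrom_length Optional chromosome length in bp, used only when
#'   `text` is a bare chromosome name.
#' @return A [GenomicInterval].
#' @examples
#' parse_interval("chr1:123,456-456,789")
#' @export
parse_interval <- function(text, chrom_length = NULL) {
  if (!is_scalar_string(text) || !nzchar(text)) {
    stop_user("interval must be a non-empty string")
  }
  if (!grepl(":", text, fixed = TRUE)) {
    if (is.null(chrom_length)) {
      stop_user("interval '%s' names a whole chromosome but no chromosome length was supplied",
                text)
    }
    return(GenomicInterval(text, 0, chrom_length))
  }
  m <- regexec("^([^:]+):([0-9][0-9,]*)-([0-9][0-9,]*)$", text)
  parts <- regmatches(text, m)[[1]]
  if (length(parts) != 4L) {
    if (!grepl("-", sub("^[^:]*:", "", text), fixed = TRUE)) {
      stop_user("malformed interval '%s': missing '-' between start and end", text)
    }
    stop_user("malformed interval '%s': expected <chrom>:<start>-<end> with numeric bounds",
              text)
  }
  chrom <- parts[2L]
  start1 <- as.numeric(gsub(",", "", parts[3L], fixed = TRUE))
  end1 <- as.numeric(gsub(",", "", parts[4L], fixed = TRUE))
  if (start1 < 1) stop_user("interval start '%s' must be >= 1 (1-based convention)", parts[3L])
  if (start1 > end1) {
    stop_user("interval start '%s' exceeds end '%s'", parts[3L], parts[4L])
  }
  GenomicInterval(chrom, start1 - 1, end1)
}

#' Format an interval in browser convention
#'
#' Inverse of [parse_interval()]: renders a 1-based fully-closed
#' `<chrom>:<start>-<end>` string without thousands separators, so that
#' `parse_interval(format_interval(iv))` is the identity.
#'
#' @param iv A [GenomicInterval].
#' @return A string.
#' @export
format_interval <- function(iv) {
  stopifnot(inherits(iv, "GenomicInterval"))
  sprintf("%s:%s-%s", iv$chrom,
          format(iv$start + 1, scientific = FALSE),
          format(iv$end, scientific = FALSE))
}

#' Interval overlap and containment predicates
#'
#' `overlaps()` tests whether two intervals share at least one base
#' (half-open intersection non-empty): same chromosome and
#' `a$start < b$end && b$start < a$end`. Abutting intervals do not overlap.
#' `contains()` tests whether `inner` lies entirely within `outer`
#' (inclusive on both flanks in the half-open algebra). Containment implies
#' overlap.
#'
#' @param a,b,outer,inner [GenomicInterval] objects.
#' @return A single logical.
#' @examples
#' overlaps(GenomicInterval("chr1", 0, 10), GenomicInterval("chr1", 10, 20)) # FALSE
#' contains(GenomicInterval("chr1", 0, 100), GenomicInterval("chr1", 0, 100)) # TRUE
#' @export
overlaps <- function(a, b) {
  stopifnot(inherits(a, "GenomicInterval"), inherits(b, "GenomicInterval"))
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

#' @rdname overlaps
#' @export
contains <- function(outer, inner) {
  stopifnot(inherits(outer, "GenomicInterval"), inherits(inner, "GenomicInterval"))
  outer$chrom == inner$chrom && outer$start <= inner$start && inner$end <= outer$end
}

#' Read and write BED3
#'
#' Minimal helpers for the three-column BED format (chrom, chromStart,
#' chromEnd; tab-separated, 0-based half-open, no header), used by the
#' fixture generator and the CLI.
#'
#' @param path File path.
#' @param x A data.frame with columns `chrom`, `start`, `end`, or a list of
#'   [GenomicInterval] objects.
#' @return `read_bed3()` returns a data.frame with columns `chrom`, `start`,
#'   `end`; `write_bed3()` returns `path` invisibly.
#' @export
read_bed3 <- function(path) {
  if (!file.exists(path)) stop_user("BED file '%s' does not exist", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "numeric", "numeric"),
                          col.names = c("chrom", "start", "end"))
  bad <- which(df$start < 0 | df$start >= df$end)
  if (length(bad)) stop_user("BED line %d has an invalid span", bad[1L])
  df
}

#' @rdname read_bed3
#' @export
write_bed3 <- function(x, path) {
  if (is.list(x) && !is.data.frame(x) && all(vapply(x, inherits, TRUE, "GenomicInterval"))) {
    x <- data.frame(chrom = vapply(x, `[[`, "", "chrom"),
                    start = vapply(x, `[[`, 0, "start"),
                    end = vapply(x, `[[`, 0, "end"))
  }
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  utils::write.table(format(x[c("chrom", "start", "end")], scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
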