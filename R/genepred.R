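# genePred gene models: exon / CDS / intron interval derivation.

parse_comma_ints <- function(text, field) {
  if (is.numeric(text)) return(as.numeric(text))
  if (!is_scalar_string(text)) stop_user("field '%s' must be a comma-separated integer list", field)
  trimmed <- sub(",$", "", text)  # UCSC dumps carry a trailing comma
  if (!nzchar(trimmed)) stop_user("field '%s' is empty", field)
  parts <- strsplit(trimmed, ",", fixed = TRUE)[[1L]]
  vals <- suppressWarnings(as.numeric(parts))
  if (anyNA(vals)) stop_user("field '%s' contains a non-integer entry '%s'",
                             field, parts[which(is.na(vals))[1L]])
  vals
}

#' Construct a genePred gene model record
#'
#' Builds a validated gene model from the genePred column set: transcript
#' span (`txStart`/`txEnd`), coding span (`cdsStart`/`cdsEnd`,
#' equal for non-coding transcripts), strand, and parallel exon start/end
#' lists (numeric vectors, or the comma-separated text blobs of a UCSC
#' table dump, tolerant of the conventional trailing comma). All
#' coordinates are 0-based half-open. Records violating the genePred
#' invariants — mismatched exon list lengths, unsorted or overlapping
#' exons, exons outside the transcript, CDS outside the transcript — are
#' rejected with an error naming the offending field; nothing is repaired.
#'
#' @param x For `as_genepred()`: a named list, one-row data.frame, or
#'   `ucsc_record` (e.g. a row fetched from a refGene-style table) carrying
#'   the genePred fields.
#' @param name,chrom,strand,txStart,txEnd,cdsStart,cdsEnd,exonStarts,exonEnds
#'   genePred fields; `strand` is `"+"` or `"-"`.
#' @param exonCount Optional; checked against the exon lists when given.
#' @return An object of class `genepred`.
#' @seealso [exons()], [cdss()], [introns()]
#' @export
genepred_record <- function(name = NA_character_, chrom, strand, txStart, txEnd,
                            cdsStart, cdsEnd, exonStarts, exonEnds,
                            exonCount = NULL) {
  exonStarts <- parse_comma_ints(exonStarts, "exonStarts")
  exonEnds <- parse_comma_ints(exonEnds, "exonEnds")
  g <- structure(list(name = name, chrom = chrom, strand = strand,
                      txStart = as.numeric(txStart), txEnd = as.numeric(txEnd),
                      cdsStart = as.numeric(cdsStart), cdsEnd = as.numeric(cdsEnd),
                      exonCount = length(exonStarts),
                      exonStarts = exonStarts, exonEnds = exonEnds),
                 class = "genepred")
  if (!is.null(exonCount) && exonCount != g$exonCount) {
    stop_user("exonCount (%s) disagrees with the exonStarts list length (%d)",
              format(exonCount), g$exonCount)
  }
  validate_genepred(g)
  g
}

#' @rdname genepred_record
#' @export
as_genepred <- function(x) {
  if (inherits(x, "genepred")) return(x)
  if (inherits(x, "ucsc_record")) x <- unclass(x)
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop_user("as_genepred() expects exactly one row")
    x <- as.list(x)
  }
  need <- c("chrom", "strand", "txStart", "txEnd", "cdsStart", "cdsEnd",
            "exonStarts", "exonEnds")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop_user("missing genePred field(s): %s", paste(missing, collapse = ", "))
  }
  genepred_record(name = x$name %||% NA_character_,
                  chrom = x$chrom, strand = x$strand,
                  txStart = x$txStart, txEnd = x$txEnd,
                  cdsStart = x$cdsStart, cdsEnd = x$cdsEnd,
                  exonStarts = x$exonStarts, exonEnds = x$exonEnds,
                  exonCount = x$exonCount)
}

validate_genepred <- function(g) {
  if (!is_scalar_string(g$chrom) || !nzchar(g$chrom)) stop_user("invalid field chrom")
  if (!(g$strand %in% c("+", "-"))) {
    stop_user("invalid field strand: must be '+' or '-', got '%s'", g$strand)
  }
  ns <- length(g$exonStarts)
  if (ns < 1L || ns != length(g$exonEnds)) {
    stop_user("invalid fields exonStarts/exonEnds: need equal non-empty lists")
  }
  if (any(g$exonStarts >= g$exonEnds)) stop_user("invalid field exonEnds: empty or inverted exon")
  if (ns > 1L && (is.unsorted(g$exonStarts, strictly = TRUE) ||
                  any(g$exonStarts[-1L] < g$exonEnds[-ns]))) {
    stop_user("invalid field exonStarts: exons must be sorted and non-overlapping")
  }
  if (g$exonStarts[1L] < g$txStart || g$exonEnds[ns] > g$txEnd) {
    stop_user("invalid field txStart/txEnd: exons extend outside the transcript span")
  }
  if (!(g$txStart <= g$cdsStart && g$cdsStart <= g$cdsEnd && g$cdsEnd <= g$txEnd)) {
    stop_user("invalid field cdsStart/cdsEnd: need txStart <= cdsStart <= cdsEnd <= txEnd")
  }
  invisible(g)
}

#' @export
print.genepred <- function(x, ...) {
  cat(sprintf("genePred %s %s%s [%s, %s) %d exon(s)%s\n",
              if (is.na(x$name)) "<unnamed>" else x$name, x$chrom, x$strand,
              format(x$txStart, scientific = FALSE),
              format(x$txEnd, scientific = FALSE), x$exonCount,
              if (x$cdsStart == x$cdsEnd) ", non-coding" else ""))
  invisible(x)
}

.strand_order <- function(ivs, strand) if (strand == "-") rev(ivs) else ivs

#' Exon, CDS and intron intervals of a gene model
#'
#' All three accessors return lists of [GenomicInterval] objects sorted
#' along the gene: ascending genomic order on the `+` strand, descending
#' (5' to 3' of the gene) on the `-` strand. Individual intervals always
#' keep `start < end`; only the list order reflects strand.
#'
#' * `exons()`: the exon spans.
#' * `cdss()`: the coding part of each exon — the intersection of the exon
#'   with `[cdsStart, cdsEnd)` — with empty intersections dropped; an empty
#'   list for non-coding transcripts (`cdsStart == cdsEnd`).
#' * `introns()`: the gaps between consecutive exons; empty for single-exon
#'   genes and zero-length gaps (abutting exons) omitted.
#'
#' @param g A [genepred_record()] (anything accepted by [as_genepred()]).
#' @return A list of [GenomicInterval] objects (possibly empty).
#' @export
exons <- function(g) {
  g <- as_genepred(g)
  ivs <- mapply(function(s, e) GenomicInterval(g$chrom, s, e),
                g$exonStarts, g$exonEnds, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  .strand_order(ivs, g$strand)
}

#' @rdname exons
#' @export
cdss <- function(g) {
  g <- as_genepred(g)
  if (g$cdsStart == g$cdsEnd) return(list())
  lo <- pmax(g$exonStarts, g$cdsStart)
  hi <- pmin(g$exonEnds, g$cdsEnd)
  keep <- lo < hi
  ivs <- mapply(function(s, e) GenomicInterval(g$chrom, s, e),
                lo[keep], hi[keep], SIMPLIFY = FALSE, USE.NAMES = FALSE)
  .strand_order(ivs, g$strand)
}

#' @rdname exons
#' @export
introns <- function(g) {
  g <- as_genepred(g)
  n <- length(g$exonStarts)
  if (n < 2L) return(list())
  gap_s <- g$exonEnds[-n]
  gap_e <- g$exonStarts[-1L]
  keep <- gap_s < gap_e
  ivs <- mapply(function(s, e) GenomicInterval(g$chrom, s, e),
                gap_s[keep], gap_e[keep], SIMPLIFY = FALSE, USE.NAMES = FALSE)
  .strand_order(ivs, g$strand)
}

#' Read a genePred text dump
#'
#' Reads tab-separated genePred text: the ten core columns (name, chrom,
#' strand, txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts,
#' exonEnds); extra trailing columns are ignored. No header line.
#'
#' @param path File path.
#' @return A data.frame with the ten core columns; rows are valid inputs to
#'   [as_genepred()].
#' @export
read_genepred <- function(path) {
  if (!file.exists(path)) stop_user("genePred file '%s' does not exist", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 10L) stop_user("genePred file '%s' has %d columns; 10 required", path, ncol(df))
  df <- df[, 1:10]
  names(df) <- c("name", "chrom", "strand", "txStart", "txEnd",
                 "cdsStart", "cdsEnd", "exonCount", "exonStarts", "exonEnds")
  for (col in c("txStart", "txEnd", "cdsStart", "cdsEnd", "exonCount")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}
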