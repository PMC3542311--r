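# 2bit packed genome sequence archives.
#
# Layout (all integers 32-bit in the archive's byte order):
#   header:  signature 0x1A412743, version 0, sequenceCount, reserved 0
#   index:   per sequence: nameSize (1 byte), name, record offset
#   record:  dnaSize, nBlockCount, nBlockStarts[], nBlockSizes[],
#            maskBlockCount, maskBlockStarts[], maskBlockSizes[],
#            reserved, packed DNA (4 bases/byte, first base in the two
#            highest-order bits; T=0 C=1 A=2 G=3)

.TB_SIG <- 0x1A412743

.tb_lookup <- local({
  codes <- rep(NA_integer_, 256L)
  set <- function(ch, v) as.integer(charToRaw(ch)) + 1L
  codes[set("T")] <- 0L; codes[set("t")] <- 0L
  codes[set("C")] <- 1L; codes[set("c")] <- 1L
  codes[set("A")] <- 2L; codes[set("a")] <- 2L
  codes[set("G")] <- 3L; codes[set("g")] <- 3L
  codes[set("N")] <- 0L; codes[set("n")] <- 0L  # unobservable filler under N blocks
  isn <- rep(FALSE, 256L)
  isn[c(set("N"), set("n"))] <- TRUE
  ismask <- rep(FALSE, 256L)
  for (ch in c("a", "c", "g", "t", "n")) ismask[set(ch)] <- TRUE
  list(codes = codes, isn = isn, ismask = ismask)
})

# (start, size) runs of TRUE, 0-based.
.tb_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  cbind(start = starts[r$values], size = r$lengths[r$values])
}

.tb_r_u32 <- function(raw, pos, n, endian, what) {
  if (n == 0L) return(numeric(0))
  if (pos + 4 * n - 1 > length(raw)) {
    stop_user("truncated 2bit file while reading %s", what)
  }
  v <- readBin(raw[pos:(pos + 4 * n - 1)], "integer", n = n, size = 4L, endian = endian)
  v <- as.numeric(v)
  v[v < 0] <- v[v < 0] + 2^32
  v
}

#' Open a 2bit genome sequence archive
#'
#' Parses the header and sequence index eagerly; per-sequence records
#' (N blocks, mask blocks, packed DNA) are parsed lazily on first access and
#' cached. Byte order is auto-detected from the signature, so archives
#' written on either endianness are readable.
#'
#' @param path Path to a `.2bit` file.
#' @return An object of class `twobit_archive`.
#' @seealso [twobit_subseq()], [twobit_write()]
#' @export
twobit_open <- function(path) {
  if (!is_scalar_string(path) || !file.exists(path)) {
    stop_user("2bit file '%s' does not exist", path)
  }
  size <- file.size(path)
  if (size < 16) {
    stop_user("truncated 2bit file '%s': %d bytes is smaller than the 16-byte header",
              path, size)
  }
  raw <- readBin(path, "raw", n = size)
  sig_le <- readBin(raw[1:4], "integer", size = 4L, endian = "little")
  sig_be <- readBin(raw[1:4], "integer", size = 4L, endian = "big")
  endian <- if (sig_le == .TB_SIG) "little" else if (sig_be == .TB_SIG) "big" else {
    stop_user("'%s' is not a 2bit file: bad signature", path)
  }
  version <- .tb_r_u32(raw, 5, 1L, endian, "header version")
  if (version != 0) {
    stop_user("unsupported 2bit version %d (only version 0 is supported)", version)
  }
  count <- .tb_r_u32(raw, 9, 1L, endian, "sequence count")
  reserved <- .tb_r_u32(raw, 13, 1L, endian, "header reserved field")
  if (reserved != 0) stop_user("corrupt 2bit header: reserved field is non-zero")

  names <- character(count)
  offsets <- numeric(count)
  pos <- 17
  for (i in seq_len(count)) {
    if (pos > length(raw)) stop_user("truncated 2bit file while reading sequence index")
    nlen <- as.integer(raw[pos])
    if (pos + nlen + 4 > length(raw) + 1) {
      stop_user("truncated 2bit file while reading sequence index")
    }
    names[i] <- rawToChar(raw[(pos + 1):(pos + nlen)])
    offsets[i] <- .tb_r_u32(raw, pos + nlen + 1, 1L, endian, "sequence index offset")
    pos <- pos + nlen + 5
  }
  if (anyDuplicated(names)) stop_user("corrupt 2bit index: duplicate sequence names")
  if (any(offsets < 16 | offsets >= size)) {
    stop_user("corrupt 2bit index: record offset outside the file")
  }

  ar <- new.env(parent = emptyenv())
  ar$path <- path
  ar$raw <- raw
  ar$endian <- endian
  ar$index <- data.frame(name = names, offset = offsets, stringsAsFactors = FALSE)
  ar$records <- new.env(parent = emptyenv())
  class(ar) <- "twobit_archive"
  ar
}

#' @export
print.twobit_archive <- function(x, ...) {
  cat(sprintf("2bit archive '%s' (%s-endian): %d sequence(s)\n",
              x$path, x$endian, nrow(x$index)))
  invisible(x)
}

# Lazy record parse with caching.
.tb_record <- function(ar, name) {
  stopifnot(inherits(ar, "twobit_archive"))
  if (!is.null(ar$records[[name]])) return(ar$records[[name]])
  i <- match(name, ar$index$name)
  if (is.na(i)) {
    stop_user("sequence '%s' not in archive (available: %s)", name,
              paste(ar$index$name, collapse = ", "))
  }
  raw <- ar$raw
  endian <- ar$endian
  pos <- ar$index$offset[i] + 1
  what <- function(f) sprintf("%s of sequence '%s'", f, name)
  dna_size <- .tb_r_u32(raw, pos, 1L, endian, what("dnaSize")); pos <- pos + 4
  nb <- .tb_r_u32(raw, pos, 1L, endian, what("nBlockCount")); pos <- pos + 4
  n_starts <- .tb_r_u32(raw, pos, nb, endian, what("nBlockStarts")); pos <- pos + 4 * nb
  n_sizes <- .tb_r_u32(raw, pos, nb, endian, what("nBlockSizes")); pos <- pos + 4 * nb
  mb <- .tb_r_u32(raw, pos, 1L, endian, what("maskBlockCount")); pos <- pos + 4
  m_starts <- .tb_r_u32(raw, pos, mb, endian, what("maskBlockStarts")); pos <- pos + 4 * mb
  m_sizes <- .tb_r_u32(raw, pos, mb, endian, what("maskBlockSizes")); pos <- pos + 4 * mb
  .tb_r_u32(raw, pos, 1L, endian, what("reserved field")); pos <- pos + 4
  n_bytes <- ceiling(dna_size / 4)
  if (pos + n_bytes - 1 > length(raw)) {
    stop_user("truncated 2bit file while reading %s", what("packed DNA"))
  }
  rec <- list(dna_size = dna_size,
              n_starts = n_starts, n_sizes = n_sizes,
              m_starts = m_starts, m_sizes = m_sizes,
              packed_pos = pos)
  ar$records[[name]] <- rec
  rec
}

#' Sequence names and lengths in an archive
#'
#' @param archive A [twobit_open()] archive.
#' @param name Sequence name.
#' @return `twobit_sequence_names()` returns a character vector in file
#'   order; `twobit_sequence_length()` a single number of base pairs.
#' @export
twobit_sequence_names <- function(archive) {
  stopifnot(inherits(archive, "twobit_archive"))
  archive$index$name
}

#' @rdname twobit_sequence_names
#' @export
twobit_sequence_length <- function(archive, name) {
  .tb_record(archive, name)$dna_size
}

#' Extract a subsequence from a 2bit archive
#'
#' Decodes the packed DNA over a 0-based half-open span. Positions covered
#' by an N block yield `N`; with `masked = TRUE` (the default, since these
#' archives normally carry repeat soft-masking) positions inside mask blocks
#' are reported in lowercase (an N inside a mask block becomes `n`).
#'
#' @param archive A [twobit_open()] archive.
#' @param name Sequence name.
#' @param start,end 0-based half-open span in bp, within `[0, dnaSize]`.
#' @param masked Report soft-masked positions in lowercase?
#' @return A character string of `end - start` bases over
#'   `{A,C,G,T,N,a,c,g,t,n}`.
#' @export
twobit_subseq <- function(archive, name, start, end, masked = TRUE) {
  rec <- .tb_record(archive, name)
  if (!is_whole(start) || !is_whole(end) || start < 0 || start >= end ||
      end > rec$dna_size) {
    stop_user("span [%s, %s) is outside [0, %s] for sequence '%s'",
              format(start), format(end),
              format(rec$dna_size, scientific = FALSE), name)
  }
  b0 <- start %/% 4
  b1 <- (end - 1) %/% 4
  bytes <- as.integer(archive$raw[(rec$packed_pos + b0):(rec$packed_pos + b1)])
  codes <- rbind(bytes %/% 64L, (bytes %/% 16L) %% 4L, (bytes %/% 4L) %% 4L, bytes %% 4L)
  chars <- c("T", "C", "A", "G")[as.vector(codes) + 1L]
  o <- start - b0 * 4
  x <- chars[(o + 1):(o + end - start)]
  for (k in seq_along(rec$n_starts)) {
    lo <- max(rec$n_starts[k], start)
    hi <- min(rec$n_starts[k] + rec$n_sizes[k], end)
    if (lo < hi) x[(lo - start + 1):(hi - start)] <- "N"
  }
  if (isTRUE(masked)) {
    for (k in seq_along(rec$m_starts)) {
      lo <- max(rec$m_starts[k], start)
      hi <- min(rec$m_starts[k] + rec$m_sizes[k], end)
      if (lo < hi) {
        rng <- (lo - start + 1):(hi - start)
        x[rng] <- tolower(x[rng])
      }
    }
  }
  paste(x, collapse = "")
}

.tb_encode <- function(s, name) {
  r <- charToRaw(s)
  ri <- as.integer(r) + 1L
  codes <- .tb_lookup$codes[ri]
  if (anyNA(codes)) {
    p <- which(is.na(codes))[1L]
    stop_user("illegal character '%s' at position %d of sequence '%s'",
              substr(s, p, p), p, name)
  }
  n <- length(codes)
  pad <- (-n) %% 4
  codes <- c(codes, integer(pad))
  m <- matrix(codes, nrow = 4L)
  list(dna_size = n,
       n_blocks = .tb_runs(.tb_lookup$isn[ri]),
       m_blocks = .tb_runs(.tb_lookup$ismask[ri]),
       packed = as.raw(m[1L, ] * 64L + m[2L, ] * 16L + m[3L, ] * 4L + m[4L, ]))
}

#' Write a 2bit archive
#'
#' Encodes named DNA strings into a version-0, little-endian 2bit file.
#' Lowercase runs become mask blocks and `N`/`n` runs become N blocks, so
#' `twobit_subseq(..., masked = TRUE)` over the full span reproduces the
#' input exactly. Bases under N blocks are stored as code 0; readers never
#' expose them, so the choice is unobservable.
#'
#' @param path Output file path.
#' @param sequences Named character vector of non-empty DNA strings over
#'   `{A,C,G,T,N}` in either case. Names must be unique and at most 255
#'   bytes.
#' @param .byte_order Archive byte order; the default (and the only
#'   documented behaviour) is little-endian. Big-endian output exists to
#'   exercise the reader's byte-order detection.
#' @return `path`, invisibly.
#' @export
twobit_write <- function(path, sequences, .byte_order = c("little", "big")) {
  endian <- match.arg(.byte_order)
  if (!is.character(sequences) || length(sequences) == 0L) {
    stop_user("sequences must be a non-empty named character vector")
  }
  nms <- names(sequences)
  if (is.null(nms) || any(!nzchar(nms)) || anyDuplicated(nms)) {
    stop_user("sequence names must be unique and non-empty")
  }
  if (any(nchar(nms, type = "bytes") > 255L)) {
    stop_user("sequence names must be at most 255 bytes")
  }
  if (any(!nzchar(sequences))) stop_user("sequences must be non-empty")

  recs <- mapply(.tb_encode, sequences, nms, SIMPLIFY = FALSE)
  name_raw <- lapply(nms, charToRaw)
  index_size <- sum(vapply(name_raw, length, 1L)) + 5L * length(nms)
  rec_size <- function(r) {
    4 * (4 + 2 * nrow(r$n_blocks) + 2 * nrow(r$m_blocks)) + length(r$packed)
  }
  offsets <- 16 + index_size + cumsum(c(0, utils::head(vapply(recs, rec_size, 0), -1L)))

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = endian)
  w32(.TB_SIG)
  w32(0L)
  w32(length(sequences))
  w32(0L)
  for (i in seq_along(recs)) {
    writeBin(as.raw(length(name_raw[[i]])), con)
    writeBin(name_raw[[i]], con)
    w32(offsets[i])
  }
  for (r in recs) {
    w32(r$dna_size)
    w32(nrow(r$n_blocks))
    w32(r$n_blocks[, "start"])
    w32(r$n_blocks[, "size"])
    w32(nrow(r$m_blocks))
    w32(r$m_blocks[, "start"])
    w32(r$m_blocks[, "size"])
    w32(0L)
    writeBin(r$packed, con)
  }
  invisible(path)
}
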