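#' The hierarchical bin scheme
#'
#' UCSC-style tables index genomic features with a five-level hierarchy of
#' bins spanning 512 Mbase, 64 Mbase, 8 Mbase, 1 Mbase and 128 kbase (exact
#' powers of two: 2^29 down to 2^17, each level 8x finer than the previous).
#' A feature is stored in the smallest bin that encompasses it, so a range
#' query only needs to inspect the bins whose extent intersects the query
#' window.
#'
#' @return A list with elements `level_spans` (bp, coarsest to finest),
#'   `level_offsets` (first bin number per level), `first_shift` (17),
#'   `next_shift` (3) and `max_position` (2^29).
#' @examples
#' bin_scheme()$level_spans
#' @export
bin_scheme <- function() {
  list(level_spans = 2^c(29, 26, 23, 20, 17),
       level_offsets = c(0L, 1L, 9L, 73L, 585L),
       first_shift = 17L,
       next_shift = 3L,
       max_position = 2^29)
}

# Offsets ordered finest -> coarsest for the shift walk.
.bin_offsets_fine_first <- c(585L, 73L, 9L, 1L, 0L)

check_bin_coords <- function(start, end) {
  if (!is_whole(start) || !is_whole(end)) {
    stop_user("bin coordinates must be whole numbers")
  }
  if (start < 0 || start >= end) {
    stop_user("invalid interval [%s, %s): need 0 <= start < end",
              format(start), format(end))
  }
  if (end > 2^29) {
    stop_user("end %s exceeds 2^29; the standard five-level bin scheme covers at most 512 Mbase",
              format(end, scientific = FALSE))
  }
}

#' Smallest enclosing bin for a feature
#'
#' Returns the number of the smallest-span bin that fully contains the
#' 0-based half-open interval `[start, end)` — the bin in which a
#' UCSC-style table stores the feature's `bin` column.
#'
#' @param start 0-based inclusive start (bp), `< 2^29`.
#' @param end 0-based exclusive end (bp), `<= 2^29`.
#' @return A single integer bin number in `[0, 4680]`.
#' @examples
#' bin_from_interval(0, 131072)  # fits the first 128kb bin: 585
#' bin_from_interval(0, 131073)  # straddles two finest bins: 73
#' @export
bin_from_interval <- function(start, end) {
  check_bin_coords(start, end)
  s <- floor(start / 2^17)
  e <- floor((end - 1) / 2^17)
  for (off in .bin_offsets_fine_first) {
    if (s == e) return(as.integer(off + s))
    s <- s %/% 8
    e <- e %/% 8
  }
  stop("unreachable: interval within 2^29 must resolve to a bin") # nocov
}

#' Candidate bins for an interval query
#'
#' Returns every bin, at every level, whose extent intersects
#' `[start, end)`. Any feature stored via [bin_from_interval()] that
#' overlaps the window has its bin in this list, which is what makes a
#' `bin IN (...)` SQL clause a pure optimization (it never changes the
#' result set).
#'
#' @inheritParams bin_from_interval
#' @return Sorted, duplicate-free integer vector of bin numbers. Always
#'   includes bin 0; has exactly 5 elements when the interval lies within a
#'   single 128kb bin.
#' @examples
#' bins_overlapping(0, 131072)  # c(0, 1, 9, 73, 585)
#' @export
bins_overlapping <- function(start, end) {
  check_bin_coords(start, end)
  s <- floor(start / 2^17)
  e <- floor((end - 1) / 2^17)
  out <- integer(0)
  for (off in .bin_offsets_fine_first) {
    out <- c(out, off + seq.int(s, e))
    s <- s %/% 8
    e <- e %/% 8
  }
  sort(unique(as.integer(out)))
}
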