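#' Circular genome intervals
#'
#' Internal coordinates are 0-based half-open. An interval on a circle of
#' length `L` either lies within the linear sequence (`wraps = FALSE`,
#' `0 <= start < end <= L`) or crosses the origin (`wraps = TRUE`, in which
#' case it covers `[start, L) + [0, end)` and `end <= start`).
#'
#' @param start 0-based inclusive start (bp).
#' @param end exclusive end (bp).
#' @param wraps does the interval cross the origin?
#' @return A list of class `"circ_interval"` with fields `start`, `end`,
#'   `wraps`.
#' @examples
#' circ_interval(0, 303)
#' circ_interval(950, 30, wraps = TRUE)
#' @export
circ_interval <- function(start, end, wraps = FALSE) {
  start <- as.integer(start); end <- as.integer(end)
  if (start < 0) stop("interval start must be >= 0")
  if (!wraps && start >= end)
    stop("non-wrapping interval requires start < end")
  if (wraps && end > start)
    stop("wrapping interval requires end <= start")
  structure(list(start = start, end = end, wraps = isTRUE(wraps)),
            class = "circ_interval")
}

#' @export
print.circ_interval <- function(x, ...) {
  cat(sprintf("[%d, %d)%s\n", x$start, x$end,
              if (x$wraps) " (wraps origin)" else ""))
  invisible(x)
}

#' Build an interval from a start and a length
#'
#' @param start 0-based start on the circle (may exceed the genome length;
#'   it is reduced modulo `genome_length`).
#' @param len feature length in bp.
#' @param genome_length circle length in bp.
#' @param circular if `FALSE` the feature must fit without wrapping.
#' @return A [circ_interval()].
#' @export
interval_from_length <- function(start, len, genome_length, circular = TRUE) {
  start <- as.integer(start) %% as.integer(genome_length)
  len <- as.integer(len)
  if (len < 1) stop("len must be >= 1")
  if (len > genome_length) stop("feature longer than the genome")
  end <- start + len
  if (end <= genome_length) return(circ_interval(start, end))
  if (!circular) stop("feature extends past the end of a linear genome")
  circ_interval(start, end - genome_length, wraps = TRUE)
}

#' Interval length on a circle
#' @param iv a [circ_interval()].
#' @param genome_length circle length in bp.
#' @return Length in bp.
#' @export
interval_length <- function(iv, genome_length) {
  if (!iv$wraps) iv$end - iv$start
  else (genome_length - iv$start) + iv$end
}

# Decompose into 1 or 2 linear [start, end) segments (matrix, one row each).
interval_segments <- function(iv, genome_length) {
  if (!iv$wraps) {
    matrix(c(iv$start, iv$end), ncol = 2)
  } else {
    rbind(c(iv$start, genome_length),
          if (iv$end > 0) c(0L, iv$end))
  }
}

#' Gap and overlap between two intervals on a circle
#'
#' Computes the length of the intersection of two features on the same
#' circle and, when they do not intersect, the minimal separating distance
#' (in either direction around the circle). Strand plays no role: proximity
#' between an ORF and a conserved gene is measured on genomic position
#' alone.
#'
#' @param a,b [circ_interval()] objects on the same circle.
#' @param genome_length circle length in bp.
#' @return A list with integer fields `gap_bp` and `overlap_bp`. Exactly one
#'   of them is positive, except for abutting features where both are 0.
#' @examples
#' circular_distance(circ_interval(0, 100), circ_interval(287, 400), 1000)
#' @export
circular_distance <- function(a, b, genome_length) {
  genome_length <- as.integer(genome_length)
  if (genome_length <= 0) stop("genome_length must be positive")
  sa <- interval_segments(a, genome_length)
  sb <- interval_segments(b, genome_length)
  ov <- 0L
  for (i in seq_len(nrow(sa))) for (j in seq_len(nrow(sb))) {
    ov <- ov + max(0L, min(sa[i, 2], sb[j, 2]) - max(sa[i, 1], sb[j, 1]))
  }
  if (ov > 0) return(list(gap_bp = 0L, overlap_bp = as.integer(ov)))
  gap <- genome_length
  for (i in seq_len(nrow(sa))) for (j in seq_len(nrow(sb))) {
    d1 <- (sb[j, 1] - sa[i, 2]) %% genome_length  # a then b clockwise
    d2 <- (sa[i, 1] - sb[j, 2]) %% genome_length  # b then a clockwise
    gap <- min(gap, d1, d2)
  }
  list(gap_bp = as.integer(gap), overlap_bp = 0L)
}

# Shift an interval by -offset modulo L (used when rotating the origin).
interval_shift <- function(iv, offset, genome_length) {
  len <- interval_length(iv, genome_length)
  interval_from_length((iv$start - offset) %% genome_length, len, genome_length)
}
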