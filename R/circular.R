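#' Circular interval length
#'
#' Length of a 1-based inclusive interval on a circular chromosome.
#' `end < start` denotes a feature wrapping across the origin.
#'
#' @param start,end 1-based inclusive positions.
#' @param genome_length Length of the circular chromosome.
#' @return Integer length in `[1, genome_length]`.
#' @examples
#' circular_length(5, 9, 100)   # 5
#' circular_length(99, 2, 100)  # 4, wraps the origin
#' @export
circular_length <- function(start, end, genome_length) {
  start <- as.integer(start); end <- as.integer(end)
  L <- as.integer(genome_length)
  if (any(start < 1L | start > L | end < 1L | end > L))
    stop("coordinates out of range [1, ", L, "]")
  ifelse(end >= start, end - start + 1L, L - start + 1L + end)
}

#' Enumerate the positions covered by a circular interval
#' @inheritParams circular_length
#' @return Integer vector of covered 1-based positions, 5' to 3'.
#' @export
circular_positions <- function(start, end, genome_length) {
  n <- circular_length(start, end, genome_length)
  ((seq.int(start, length.out = n) - 1L) %% genome_length) + 1L
}

# Split a circular interval into 1 or 2 linear [start, end] pieces.
circ_pieces <- function(start, end, L) {
  start <- as.integer(start); end <- as.integer(end); L <- as.integer(L)
  if (end >= start) matrix(c(start, end), ncol = 2)
  else matrix(c(start, L, 1L, end), ncol = 2, byrow = TRUE)
}

#' Overlap (in bases) of two circular intervals
#' @param s1,e1,s2,e2 1-based inclusive endpoints of the two intervals.
#' @param genome_length Length of the circular chromosome.
#' @return Number of shared positions.
#' @export
circular_overlap <- function(s1, e1, s2, e2, genome_length) {
  p1 <- circ_pieces(s1, e1, genome_length)
  p2 <- circ_pieces(s2, e2, genome_length)
  ov <- 0L
  for (i in seq_len(nrow(p1))) for (j in seq_len(nrow(p2))) {
    lo <- max(p1[i, 1], p2[j, 1]); hi <- min(p1[i, 2], p2[j, 2])
    if (hi >= lo) ov <- ov + (hi - lo + 1L)
  }
  ov
}

#' Signed circular gap between a feature end and a downstream start
#'
#' Number of bases strictly between `from_end` and `to_start` walking
#' 5' to 3' around the circle; distances longer than half the genome are
#' reported as negative (an overlap of the start into the upstream
#' feature).
#'
#' @param from_end End position of the upstream feature.
#' @param to_start Start position of the downstream feature.
#' @param genome_length Length of the circular chromosome.
#' @return Signed integer gap; negative values are overlaps.
#' @export
circular_gap <- function(from_end, to_start, genome_length) {
  L <- as.integer(genome_length)
  d <- (as.integer(to_start) - as.integer(from_end) - 1L) %% L
  ifelse(d > L %/% 2L, d - L, d)
}

#' Minimal circular distance between two positions
#' @param a,b 1-based positions.
#' @param genome_length Length of the circular chromosome.
#' @return Non-negative integer distance.
#' @export
circular_distance <- function(a, b, genome_length) {
  L <- as.integer(genome_length)
  d <- (as.integer(a) - as.integer(b)) %% L
  pmin(d, L - d)
}
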