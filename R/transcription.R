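# Strand-aware transcription evidence: single-strand transcription test,
# transcribed intergenic regions (lncmtRNA candidates) and coverage
# drop-offs marking cleavage/start sites.

#' Construct a stranded per-base coverage track
#'
#' @param genome_id Genome the track belongs to.
#' @param sense Non-negative per-position depth on the sense strand.
#' @param antisense Per-position antisense depth; defaults to all zero
#'   (nondirectional libraries carry no strand information and are
#'   represented this way).
#' @return Object of class `coverage_track`.
#' @export
coverage_track <- function(genome_id, sense, antisense = rep(0, length(sense))) {
  if (length(sense) != length(antisense))
    stop("sense and antisense vectors must have equal length")
  if (any(sense < 0) || any(antisense < 0)) stop("depths must be >= 0")
  structure(list(genome_id = genome_id,
                 sense = as.numeric(sense),
                 antisense = as.numeric(antisense)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s: %d bp, mean sense %.1fx, mean antisense %.2fx\n",
              x$genome_id, length(x$sense), mean(x$sense), mean(x$antisense)))
  invisible(x)
}

#' Read a per-base coverage TSV (columns: pos, sense, antisense)
#'
#' Positions absent from the file get depth 0 on both strands.
#'
#' @param path TSV file with header `pos`, `sense`, `antisense`.
#' @param genome The `mito_genome` the track covers.
#' @return A [coverage_track()].
#' @export
read_coverage_tsv <- function(path, genome) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  L <- genome_length(genome)
  if (any(df$pos < 1L | df$pos > L)) stop("coverage position out of range")
  sense <- antisense <- numeric(L)
  sense[df$pos] <- df$sense
  antisense[df$pos] <- df$antisense
  coverage_track(genome$id, sense, antisense)
}

#' Write a coverage track as TSV
#' @param track A `coverage_track`.
#' @param path Output file.
#' @export
write_coverage_tsv <- function(track, path) {
  utils::write.table(
    data.frame(pos = seq_along(track$sense), sense = track$sense,
               antisense = track$antisense),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pair of single-strand bedGraph files into a coverage track
#'
#' bedGraph intervals are 0-based half-open; they are expanded to per-base
#' 1-based depths at the boundary.
#'
#' @param sense_path,antisense_path bedGraph files for the two strands.
#'   `antisense_path = NULL` (nondirectional library) yields an all-zero
#'   antisense vector.
#' @param genome The covered `mito_genome`.
#' @return A [coverage_track()].
#' @export
read_bedgraph_pair <- function(sense_path, antisense_path, genome) {
  L <- genome_length(genome)
  expand <- function(path) {
    v <- numeric(L)
    if (is.null(path)) return(v)
    bg <- utils::read.table(path, header = FALSE, sep = "\t",
                            col.names = c("chrom", "start", "end", "depth"))
    if (any(bg$start < 0L | bg$end > L)) stop("bedGraph interval out of range")
    for (i in seq_len(nrow(bg)))
      v[(bg$start[i] + 1L):bg$end[i]] <- bg$depth[i]
    v
  }
  coverage_track(genome$id, expand(sense_path), expand(antisense_path))
}

# logical mask of positions covered by features of given types
.feature_mask <- function(table, L, types) {
  m <- logical(L)
  sel <- table[table$type %in% types, , drop = FALSE]
  for (i in seq_len(nrow(sel)))
    m[circular_positions(sel$start[i], sel$end[i], L)] <- TRUE
  m
}

#' Fraction of coverage on the sense strand
#'
#' The single-strand transcription test: the fraction of total depth that
#' lies on the sense strand. rRNA loci are excluded by default because
#' antisense signal there is expected rRNA carry-over in polyA-selected
#' libraries, not evidence of antisense transcription.
#'
#' @param track A `coverage_track`.
#' @param annotations A `mito_annotation` (used for the rRNA mask).
#' @param exclude_rrna Exclude positions inside rRNA features.
#' @return Fraction in `[0, 1]`, or `NA` when total depth is zero
#'   (the fraction is undefined, not 0 or 1).
#' @export
strand_fraction <- function(track, annotations, exclude_rrna = TRUE) {
  L <- length(track$sense)
  keep <- rep(TRUE, L)
  if (exclude_rrna) keep <- !.feature_mask(annotations, L, "rRNA")
  tot <- sum(track$sense[keep]) + sum(track$antisense[keep])
  if (tot == 0) return(NA_real_)
  sum(track$sense[keep]) / tot
}

# maximal circular runs of TRUE; returns data.frame(start, end) in 1-based
# circular coordinates (a run may wrap the origin). All-TRUE gives one
# full-length run flagged by attribute "full_circle".
.circular_runs <- function(v) {
  L <- length(v)
  if (all(v)) {
    out <- data.frame(start = 1L, end = L)
    attr(out, "full_circle") <- TRUE
    return(out)
  }
  if (!any(v)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge a run touching position L with a run starting at 1 (wrap)
  if (nrow(runs) > 1L && runs$end[nrow(runs)] == L && runs$start[1] == 1L) {
    runs$start[nrow(runs)] <- runs$start[nrow(runs)]
    runs$end[nrow(runs)] <- runs$end[1]
    runs <- runs[-1, , drop = FALSE]
  }
  rownames(runs) <- NULL
  runs
}

#' Call transcribed regions from sense-strand coverage
#'
#' Positions with sense depth at or above a per-base floor are segmented
#' into maximal circular runs; runs separated by no more than `merge_gap`
#' bases are merged; merged segments are kept when they are at least
#' `min_len` long and their mean depth reaches `min_mean_depth`. A region
#' is labelled `intergenic` when less than 10% of it overlaps any annotated
#' feature, else `genic-overlap`.
#'
#' @param track A `coverage_track`.
#' @param annotations A `mito_annotation`.
#' @param min_len Minimum circular region length (default 100, the
#'   conventional lncRNA length floor).
#' @param min_mean_depth Minimum mean depth of an emitted region.
#' @param merge_gap Segments closer than this are merged (default 50).
#' @param floor Per-base depth floor for segmentation (default
#'   `min_mean_depth / 2`).
#' @return `data.frame`: `start`, `end`, `length`, `mean_depth`,
#'   `max_depth`, `label`.
#' @export
call_transcribed_regions <- function(track, annotations, min_len = 100L,
                                     min_mean_depth, merge_gap = 50L,
                                     floor = min_mean_depth / 2) {
  stopifnot(min_mean_depth > 0)
  L <- length(track$sense)
  segs <- .circular_runs(track$sense >= floor)
  if (nrow(segs) == 0L)
    return(data.frame(start = integer(0), end = integer(0), length = integer(0),
                      mean_depth = numeric(0), max_depth = numeric(0),
                      label = character(0)))
  # merge segments whose circular gap is <= merge_gap
  if (nrow(segs) > 1L && is.null(attr(segs, "full_circle"))) {
    segs <- segs[order(segs$start), , drop = FALSE]
    merged <- segs[1, , drop = FALSE]
    for (i in seq.int(2L, nrow(segs))) {
      last <- nrow(merged)
      gap <- (segs$start[i] - merged$end[last] - 1L) %% L
      if (gap <= merge_gap) merged$end[last] <- segs$end[i]
      else merged <- rbind(merged, segs[i, ])
    }
    # wrap: first segment may merge into the last
    if (nrow(merged) > 1L) {
      gap <- (merged$start[1] - merged$end[nrow(merged)] - 1L) %% L
      if (gap <= merge_gap) {
        merged$start[1] <- merged$start[nrow(merged)]
        merged <- merged[-nrow(merged), , drop = FALSE]
      }
    }
    segs <- merged
  }
  ann_mask <- .feature_mask(annotations, L, .feature_types)
  out <- lapply(seq_len(nrow(segs)), function(i) {
    pos <- circular_positions(segs$start[i], segs$end[i], L)
    depth <- track$sense[pos]
    len <- length(pos)
    if (len < min_len || mean(depth) < min_mean_depth) return(NULL)
    data.frame(start = segs$start[i], end = segs$end[i], length = len,
               mean_depth = mean(depth), max_depth = max(depth),
               label = if (mean(ann_mask[pos]) < 0.10) "intergenic"
                       else "genic-overlap")
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(start = integer(0), end = integer(0), length = integer(0),
                      mean_depth = numeric(0), max_depth = numeric(0),
                      label = character(0))
  rownames(out) <- NULL
  out
}

# circular rolling means of the `window` positions ending at p (left) and
# starting at p+1 (right)
.boundary_means <- function(v, window) {
  L <- length(v)
  ext <- c(v, v, v)  # center copy is positions 1..L at offset L
  cs <- c(0, cumsum(ext))
  p <- seq_len(L) + L
  left <- (cs[p + 1L] - cs[p + 1L - window]) / window
  right <- (cs[p + 1L + window] - cs[p + 1L]) / window
  list(left = left, right = right)
}

#' Detect coverage drop-off sites (putative cleavage/start boundaries)
#'
#' For every boundary between positions p and p+1 the score
#' `log2((mean depth over the window left of the boundary + 1) /
#' (mean depth over the window right of it + 1))` is computed with circular
#' windows. Boundaries that are local extrema of the score with
#' `|score| >= min_log2` are reported, greedily thinned (strongest first)
#' so that no two reported sites are closer than `min_separation`. The +1
#' pseudocount keeps zero-coverage flanks finite.
#'
#' @param track A `coverage_track`.
#' @param window Flank width in bases (default 50).
#' @param min_log2 Minimum absolute log2 ratio (default 2).
#' @param min_separation Minimum circular distance between reported sites
#'   (default 100).
#' @return `data.frame`: `position` (boundary between `position` and
#'   `position + 1`), `log2_ratio`, `direction` (`down` when depth falls
#'   left to right, `up` when it rises).
#' @export
detect_dropoffs <- function(track, window = 50L, min_log2 = 2.0,
                            min_separation = 100L) {
  stopifnot(window >= 1L)
  v <- track$sense
  L <- length(v)
  bm <- .boundary_means(v, window)
  s <- log2((bm$left + 1) / (bm$right + 1))
  a <- abs(s)
  prev <- c(a[L], a[-L]); nxt <- c(a[-1], a[1])
  cand <- which(a >= min_log2 & a >= prev & a >= nxt)
  if (length(cand) == 0L)
    return(data.frame(position = integer(0), log2_ratio = numeric(0),
                      direction = character(0)))
  cand <- cand[order(-a[cand], cand)]
  kept <- integer(0)
  for (p in cand) {
    if (length(kept) == 0L ||
        all(circular_distance(p, kept, L) >= min_separation))
      kept <- c(kept, p)
  }
  kept <- sort(kept)
  data.frame(position = kept, log2_ratio = s[kept],
             direction = ifelse(s[kept] > 0, "down", "up"))
}

#' Match start calls to upstream coverage up-steps
#'
#' Each start call is matched to the nearest `up` drop-off site within
#' `tolerance` bases (circular distance), if any.
#'
#' @param calls Start calls from [select_start()]/[refine_starts()].
#' @param sites Drop-off sites from [detect_dropoffs()].
#' @param genome_length Circular chromosome length.
#' @param tolerance Maximum circular distance (default 10).
#' @return `calls` with columns `matched_position` and `matched_log2`
#'   (`NA` when unmatched).
#' @export
annotate_starts_with_dropoffs <- function(calls, sites, genome_length,
                                          tolerance = 10L) {
  ups <- sites[sites$direction == "up", , drop = FALSE]
  calls$matched_position <- NA_integer_
  calls$matched_log2 <- NA_real_
  if (nrow(ups) > 0L) for (i in seq_len(nrow(calls))) {
    d <- circular_distance(calls$position[i], ups$position, genome_length)
    j <- which.min(d)
    if (d[j] <= tolerance) {
      calls$matched_position[i] <- ups$position[j]
      calls$matched_log2[i] <- ups$log2_ratio[j]
    }
  }
  calls
}
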