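#' Scan the sense strand of a circular genome for ORFs
#'
#' Finds, in each of the three sense-strand reading frames read circularly
#' across the origin, the maximal stop-to-stop segments whose translation
#' (excluding the terminating stop) is at least `min_len` amino acids.
#' Segments are stop-to-stop rather than start-anchored because start
#' codons are refined afterwards from cross-species homology; every
#' in-frame occurrence of an initiator codon within the segment is
#' recorded as a candidate start. The genome is conceptually doubled for
#' the scan and an ORF can never be longer than the genome; a circular
#' frame containing no stop codon at all is emitted capped at the full
#' frame length and flagged `no_stop`.
#'
#' @param genome A [genome()].
#' @param table A [codon_table()].
#' @param min_len Minimum protein length in amino acids (default 80).
#' @return List of `mito_orf` objects, each a list with `genome_id`,
#'   `frame` (0-2), `start`/`end` (1-based circular positions of the first
#'   and last coding base, stop excluded), `length_aa`, `protein`,
#'   `candidate_starts` (data.frame: `position`, `codon`, `codon_index`)
#'   and `no_stop`.
#' @seealso [orfs_table()] for a tabular view.
#' @export
scan_orfs <- function(genome, table = codon_table(), min_len = 80L) {
  L <- genome_length(genome)
  s2 <- paste0(genome$sequence, genome$sequence)
  out <- list()
  seen <- character(0)
  for (f in 0:2) {
    at <- seq.int(f + 1L, 2L * L - 2L, by = 3L)
    codons <- substring(s2, at, at + 2L)
    stops <- which(codons %in% table$stops)
    if (length(stops) == 0L) {
      # stop-free circular frame: cap at the full frame length
      n_cod <- L %/% 3L
      if (n_cod >= min_len) {
        key <- paste0(f + 1L, ":", n_cod, ":cap")
        if (!key %in% seen) {
          seen <- c(seen, key)
          out[[length(out) + 1L]] <- .make_orf(genome, table, s2, L,
                                               nt_start = f + 1L,
                                               n_cod = n_cod, no_stop = TRUE)
        }
      }
      next
    }
    if (length(stops) < 2L) next
    for (i in seq_len(length(stops) - 1L)) {
      a <- stops[i]; b <- stops[i + 1L]
      n_cod <- b - a - 1L
      if (n_cod < min_len) next
      if (3L * n_cod > L - 3L) next        # cannot exceed the circle
      nt_start <- at[a] + 3L
      circ_start <- ((nt_start - 1L) %% L) + 1L
      key <- paste0(circ_start, ":", n_cod)
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- .make_orf(genome, table, s2, L,
                                           nt_start = nt_start,
                                           n_cod = n_cod, no_stop = FALSE)
    }
  }
  out[order(vapply(out, `[[`, integer(1), "start"))]
}

.make_orf <- function(genome, table, s2, L, nt_start, n_cod, no_stop) {
  nt <- substr(s2, nt_start, nt_start + 3L * n_cod - 1L)
  circ_start <- ((nt_start - 1L) %% L) + 1L
  circ_end <- ((circ_start - 1L + 3L * n_cod - 1L) %% L) + 1L
  at <- seq.int(1L, 3L * n_cod, by = 3L)
  codons <- substring(nt, at, at + 2L)
  is_start <- codons %in% table$start_codons
  cand <- data.frame(
    position = ((circ_start - 1L + at[is_start] - 1L) %% L) + 1L,
    codon = codons[is_start],
    codon_index = which(is_start)
  )
  structure(list(
    genome_id = genome$id,
    frame = (circ_start - 1L) %% 3L,
    start = circ_start,
    end = circ_end,
    length_aa = n_cod,
    protein = translate(nt, table),
    candidate_starts = cand,
    no_stop = no_stop
  ), class = "mito_orf")
}

#' @export
print.mito_orf <- function(x, ...) {
  cat(sprintf("<mito_orf> %s frame %d, %d..%d (%d aa, %d candidate starts)%s\n",
              x$genome_id, x$frame, x$start, x$end, x$length_aa,
              nrow(x$candidate_starts), if (x$no_stop) " [no-stop]" else ""))
  invisible(x)
}

#' Tabulate a list of ORFs
#' @param orfs List of `mito_orf` from [scan_orfs()].
#' @return `data.frame` with one row per ORF.
#' @export
orfs_table <- function(orfs) {
  data.frame(
    genome_id = vapply(orfs, `[[`, character(1), "genome_id"),
    frame = vapply(orfs, `[[`, integer(1), "frame"),
    start = vapply(orfs, `[[`, integer(1), "start"),
    end = vapply(orfs, `[[`, integer(1), "end"),
    length_aa = vapply(orfs, `[[`, integer(1), "length_aa"),
    n_candidate_starts = vapply(orfs, function(o) nrow(o$candidate_starts), integer(1)),
    no_stop = vapply(orfs, `[[`, logical(1), "no_stop"),
    protein = vapply(orfs, `[[`, character(1), "protein")
  )
}

#' The ORF overlapping an annotated locus
#'
#' Returns the ORF with maximal circular overlap with the feature, ties
#' broken in favour of the longer ORF.
#'
#' @param orfs List of `mito_orf` from the same genome.
#' @param feature One-row slice of a `mito_annotation` (or a list with
#'   `start` and `end`).
#' @param genome_length Circular chromosome length.
#' @return The best `mito_orf`, or `NULL` if none overlaps.
#' @export
orf_for_locus <- function(orfs, feature, genome_length) {
  if (length(orfs) == 0L) return(NULL)
  ov <- vapply(orfs, function(o)
    circular_overlap(o$start, o$end, feature$start, feature$end, genome_length),
    integer(1))
  if (max(ov) == 0L) return(NULL)
  best <- which(ov == max(ov))
  if (length(best) > 1L) {
    len <- vapply(orfs[best], `[[`, integer(1), "length_aa")
    best <- best[which.max(len)]
  }
  orfs[[best[1]]]
}

#' Proteins encoded by the annotated CDS features
#'
#' Translates each CDS from its annotated start through its annotated end
#' (circularly), forcing the initiator to Met and trimming at the first
#' stop. Used to provide the reference proteins that homology grouping
#' aligns against.
#'
#' @param genome A `mito_genome`.
#' @param table A `mito_annotation` for that genome.
#' @param codon_table A [codon_table()].
#' @return Named character vector, one protein per CDS gene.
#' @export
annotation_proteins <- function(genome, table, codon_table = mitocurate::codon_table()) {
  cds <- table[table$type == "CDS", , drop = FALSE]
  out <- character(nrow(cds))
  for (i in seq_len(nrow(cds))) {
    nt <- genome_subseq(genome, cds$start[i], cds$end[i])
    nt <- substr(nt, 1L, nchar(nt) - nchar(nt) %% 3L)
    aa <- translate(nt, codon_table, as_initiator = TRUE)
    out[i] <- sub("\\*.*$", "", aa)   # trim at the first stop
  }
  stats::setNames(out, cds$gene)
}
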