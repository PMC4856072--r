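# Noncoding-region catalogue, gene-length surveys, and discovery of
# candidate ORFs in transcribed intergenic regions (the putative atp8),
# with hydropathy-based transmembrane and signal-like N-terminus
# heuristics.

#' Catalogue noncoding regions of an annotated genome
#'
#' Noncoding regions are the maximal circular intervals free of CDS and
#' rRNA features. tRNAs inside an interval do not break it: they are
#' recorded as interrupting features and (by default) their bases are
#' excluded from the region length, so a long region "interrupted only by a
#' single tRNA" is reported with its noncoding length proper. Regions at
#' least `long_threshold` bases long are classed `long`, the rest `short`.
#'
#' @param table A `mito_annotation`.
#' @param genome The annotated `mito_genome` (only its length is used).
#' @param long_threshold Length separating long from short regions
#'   (default 500).
#' @param exclude_trna_length If `FALSE`, report the full span including
#'   embedded tRNAs instead.
#' @return `data.frame`: `start`, `end` (span endpoints), `length`
#'   (noncoding bases), `interrupting_features`, `flank_upstream`,
#'   `flank_downstream`, `klass`.
#' @export
noncoding_catalog <- function(table, genome, long_threshold = 500L,
                              exclude_trna_length = TRUE) {
  L <- genome_length(genome)
  blocked <- .feature_mask(table, L, c("CDS", "rRNA"))
  runs <- .circular_runs(!blocked)
  empty <- data.frame(start = integer(0), end = integer(0), length = integer(0),
                      interrupting_features = character(0),
                      flank_upstream = character(0),
                      flank_downstream = character(0), klass = character(0))
  if (nrow(runs) == 0L) return(empty)
  blockers <- table[table$type %in% c("CDS", "rRNA"), , drop = FALSE]
  trnas <- table[table$type == "tRNA", , drop = FALSE]
  out <- lapply(seq_len(nrow(runs)), function(i) {
    s <- runs$start[i]; e <- runs$end[i]
    span <- circular_length(s, e, L)
    t_ov <- vapply(seq_len(nrow(trnas)), function(j)
      circular_overlap(s, e, trnas$start[j], trnas$end[j], L), integer(1))
    inter <- trnas$gene[t_ov > 0L]
    len <- if (exclude_trna_length) span - sum(t_ov) else span
    up <- if (nrow(blockers)) {
      d <- (s - blockers$end - 1L) %% L
      blockers$gene[which.min(d)]
    } else NA_character_
    dn <- if (nrow(blockers)) {
      d <- (blockers$start - e - 1L) %% L
      blockers$gene[which.min(d)]
    } else NA_character_
    data.frame(start = s, end = e, length = len,
               interrupting_features = paste(inter, collapse = ","),
               flank_upstream = up, flank_downstream = dn,
               klass = if (len >= long_threshold) "long" else "short")
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Survey the protein length of one gene across a panel
#'
#' Protein lengths are computed from the annotated start through the last
#' residue before the stop, by circular extraction and translation.
#'
#' @param panel Named list; each element a list with `genome` and `table`.
#' @param gene Gene label to survey.
#' @param codon_table A [codon_table()].
#' @return List: `n`, `min`, `max`, `mean` (rounded to the nearest integer),
#'   `lengths` (named per-species vector in amino acids).
#' @export
survey_gene_lengths <- function(panel, gene, codon_table = mitocurate::codon_table()) {
  lens <- integer(0)
  for (sp in names(panel)) {
    tab <- panel[[sp]]$table
    row <- tab[tab$gene == gene, , drop = FALSE]
    if (nrow(row) == 0L) {
      warning("gene '", gene, "' missing from ", sp, "; excluded")
      next
    }
    prot <- annotation_proteins(panel[[sp]]$genome, row, codon_table)
    lens[sp] <- nchar(prot[[1]])
  }
  if (length(lens) == 0L) stop("gene '", gene, "' found in no table")
  list(n = length(lens), min = min(lens), max = max(lens),
       mean = as.integer(round(mean(lens))), lengths = lens)
}

#' Discover start-anchored candidate ORFs inside regions
#'
#' Unlike the genome-wide stop-to-stop scan, candidate ORFs in noncoding or
#' transcribed regions are anchored at an initiator codon, because no
#' cross-species homology exists to define their upstream extent. For each
#' region, every in-region initiator codon opening a stop-terminated frame
#' fully inside the region and encoding at least `min_len` amino acids is
#' reported (one ORF per terminating stop: the most upstream start wins).
#' Transmembrane segments ([hydropathy_tm()]) and a signal-like N-terminus
#' flag ([signal_like_nterm()]) are attached.
#'
#' @param genome A `mito_genome`.
#' @param table Its `mito_annotation` (for the upstream-gene assignment).
#' @param regions `data.frame` with `start` and `end` columns (noncoding or
#'   transcribed regions).
#' @param codon_table A [codon_table()].
#' @param min_len Minimum protein length in amino acids (default 25).
#' @return `data.frame`: `start`, `end` (ORF coordinates, stop included),
#'   `length_aa`, `start_codon`, `protein`, `after_gene`,
#'   `distance_from_after_gene`, `n_tm_segments`, `max_tm_hydropathy`,
#'   `has_signal_like_nterm`.
#' @export
discover_candidate_orfs <- function(genome, table, regions,
                                    codon_table = mitocurate::codon_table(),
                                    min_len = 25L) {
  L <- genome_length(genome)
  majors <- table[table$type %in% c("CDS", "rRNA"), , drop = FALSE]
  out <- list()
  for (r in seq_len(nrow(regions))) {
    rs <- regions$start[r]; re <- regions$end[r]
    rseq <- genome_subseq(genome, rs, re)
    n <- nchar(rseq)
    if (n < 3L * (min_len + 1L)) next
    at <- seq_len(n - 2L)
    tri <- substring(rseq, at, at + 2L)
    start_pos <- which(tri %in% codon_table$start_codons)
    claimed_stops <- character(0)
    for (i in start_pos) {
      # read codons from i until a stop, staying inside the region
      j <- i
      stop_at <- NA_integer_
      while (j + 2L <= n) {
        if (tri[j] %in% codon_table$stops) { stop_at <- j; break }
        j <- j + 3L
      }
      if (is.na(stop_at)) next
      aa_len <- (stop_at - i) %/% 3L
      if (aa_len < min_len) next
      key <- paste0(stop_at, ":", (i - 1L) %% 3L)
      if (key %in% claimed_stops) next  # a more upstream start already owns it
      claimed_stops <- c(claimed_stops, key)
      orf_start <- ((rs - 1L + i - 1L) %% L) + 1L
      orf_end <- ((rs - 1L + stop_at + 2L - 1L) %% L) + 1L
      prot <- translate(substr(rseq, i, stop_at - 1L), codon_table,
                        as_initiator = TRUE)
      tm <- if (nchar(prot) >= 19L) hydropathy_tm(prot) else
        data.frame(start_aa = integer(0), end_aa = integer(0),
                   mean_hydropathy = numeric(0))
      d <- (orf_start - majors$end - 1L) %% L
      k <- which.min(d)
      out[[length(out) + 1L]] <- data.frame(
        start = orf_start, end = orf_end, length_aa = aa_len,
        start_codon = tri[i], protein = prot,
        after_gene = if (nrow(majors)) majors$gene[k] else NA_character_,
        distance_from_after_gene = if (nrow(majors)) d[k] else NA_integer_,
        n_tm_segments = nrow(tm),
        max_tm_hydropathy = if (nrow(tm)) max(tm$mean_hydropathy) else NA_real_,
        has_signal_like_nterm = nchar(prot) >= 15L && signal_like_nterm(prot))
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(start = integer(0), end = integer(0),
                      length_aa = integer(0), start_codon = character(0),
                      protein = character(0), after_gene = character(0),
                      distance_from_after_gene = integer(0),
                      n_tm_segments = integer(0),
                      max_tm_hydropathy = numeric(0),
                      has_signal_like_nterm = logical(0))
  rownames(out) <- NULL
  out
}

#' Kyte-Doolittle hydropathy values
#' @return Named numeric vector over the 20 amino acids (unknowns score 0).
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

.kd_values <- function(protein) {
  kd <- kyte_doolittle()
  v <- kd[strsplit(toupper(protein), "")[[1]]]
  v[is.na(v)] <- 0
  unname(v)
}

#' Transmembrane segments by sliding-window hydropathy
#'
#' A hydropathy-plot heuristic standing in for a domain-database
#' prediction: window-centered Kyte-Doolittle means are computed, and
#' maximal runs of window centers at or above `threshold` are reported as
#' transmembrane segments (`start_aa`/`end_aa` are the first and last
#' qualifying centers; `mean_hydropathy` is the mean of the window scores
#' over the run, hence always at or above the threshold).
#'
#' @param protein Amino-acid string of length at least `window`.
#' @param window Window width in residues; must be odd (default 19, the
#'   standard span of a membrane-crossing helix).
#' @param threshold Window-mean hydropathy cutoff (default 1.6, the
#'   published cutoff for predicting transmembrane segments).
#' @return `data.frame`: `start_aa`, `end_aa`, `mean_hydropathy`. Empty
#'   (with a warning) when the protein is shorter than the window.
#' @export
hydropathy_tm <- function(protein, window = 19L, threshold = 1.6) {
  stopifnot(window %% 2L == 1L)
  n <- nchar(protein)
  empty <- data.frame(start_aa = integer(0), end_aa = integer(0),
                      mean_hydropathy = numeric(0))
  if (n < window) {
    warning("protein shorter than window (", n, " < ", window, ")")
    return(empty)
  }
  # hydropathy values are one-decimal: decide threshold crossings on exact
  # integer sums (x10) so ties at the cutoff are not at the mercy of
  # floating-point accumulation order
  v10 <- as.integer(round(10 * .kd_values(protein)))
  cs <- c(0L, cumsum(v10))
  h <- (window - 1L) %/% 2L
  centers <- seq.int(h + 1L, n - h)
  sums10 <- cs[centers + h + 1L] - cs[centers - h]
  scores <- sums10 / (10 * window)
  ok <- sums10 >= 10 * threshold * window - 1e-9
  if (!any(ok)) return(empty)
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  ii <- which(r$values)
  data.frame(
    start_aa = centers[starts[ii]],
    end_aa = centers[ends[ii]],
    mean_hydropathy = vapply(ii, function(k)
      mean(scores[starts[k]:ends[k]]), numeric(1)))
}

#' Signal-like N-terminus heuristic
#'
#' A rule-based stand-in for signal-peptide prediction: `TRUE` when the
#' first 30 residues contain a hydrophobic stretch of at least 7 residues
#' (every length-7 window mean Kyte-Doolittle at or above 1.6 qualifies a
#' stretch) preceded by at least one positively charged residue (K/R)
#' within the first 5 residues. A heuristic with no claim of equivalence to
#' trained signal-peptide predictors.
#'
#' @param protein Amino-acid string of length at least 15.
#' @return Logical.
#' @export
signal_like_nterm <- function(protein) {
  n <- nchar(protein)
  if (n < 15L) stop("protein too short for the N-terminus rule (need >= 15 aa)")
  v10 <- as.integer(round(10 * .kd_values(protein)))
  res <- strsplit(toupper(protein), "")[[1]]
  has_kr <- any(res[1:5] %in% c("K", "R"))
  if (!has_kr) return(FALSE)
  last_start <- min(n, 30L) - 6L
  if (last_start < 1L) return(FALSE)
  for (i in seq_len(last_start)) {
    if (sum(v10[i:(i + 6L)]) >= 10 * 1.6 * 7 - 1e-9) return(TRUE)
  }
  FALSE
}
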