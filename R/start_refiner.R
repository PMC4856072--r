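# Cross-species start-codon refinement: group homologous ORFs, multi-align
# them, and pick each gene's start as the candidate that keeps the most
# conserved alignment columns downstream while not running into the
# upstream gene.

.blosum62x_cache <- new.env(parent = emptyenv())

#' BLOSUM62 with unknown residues scored -1
#'
#' The published BLOSUM62 matrix with the `X` row/column overridden to -1
#' against everything, so unknown residues are mildly penalized rather than
#' scored by the matrix's marginal averages.
#'
#' @return Integer substitution matrix.
#' @export
blosum62x <- function() {
  if (is.null(.blosum62x_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    m["X", ] <- -1L
    m[, "X"] <- -1L
    .blosum62x_cache$m <- m
  }
  .blosum62x_cache$m
}

.sanitize_aa <- function(x, matrix = blosum62x()) {
  known <- paste(setdiff(rownames(matrix), "*"), collapse = "")
  gsub(sprintf("[^%s]", known), "X", toupper(x))
}

#' Optimal local (Smith-Waterman) protein alignment
#'
#' Exact affine-gap local alignment with BLOSUM62 and BLAST's default gap
#' costs (a gap of length k costs `gap_open + k * gap_extend`). Replaces a
#' BLASTP heuristic search with an exact computation; raw scores, not
#' E-values, are used downstream (panel sizes are tiny, so database-size
#' statistics add nothing).
#'
#' @param a,b Amino-acid strings. Residues outside the matrix alphabet are
#'   scored as `X` (-1 against everything).
#' @param matrix Substitution matrix (default [blosum62x()]).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return List with `score`, aligned strings `a_aligned`/`b_aligned`, and
#'   1-based alignment start offsets `a_start`/`b_start` (all empty/NA for
#'   a zero-score alignment).
#' @export
local_align <- function(a, b, matrix = blosum62x(), gap_open = 11, gap_extend = 1) {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("sequences must be non-empty")
  pa <- Biostrings::pairwiseAlignment(
    .sanitize_aa(a, matrix), .sanitize_aa(b, matrix), type = "local",
    substitutionMatrix = matrix, gapOpening = gap_open, gapExtension = gap_extend)
  s <- Biostrings::score(pa)
  if (s <= 0) return(list(score = 0, a_aligned = "", b_aligned = "",
                          a_start = NA_integer_, b_start = NA_integer_))
  list(score = s,
       a_aligned = as.character(Biostrings::alignedPattern(pa)),
       b_aligned = as.character(Biostrings::alignedSubject(pa)),
       a_start = BiocGenerics::start(Biostrings::pattern(pa)),
       b_start = BiocGenerics::start(Biostrings::subject(pa)))
}

# Vector of local-alignment scores of many queries against one subject.
.local_scores <- function(queries, subject, matrix = blosum62x(),
                          gap_open = 11, gap_extend = 1) {
  if (length(queries) == 0L) return(numeric(0))
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(.sanitize_aa(queries, matrix)),
    .sanitize_aa(subject, matrix),
    type = "local", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
  pmax(s, 0)
}

#' Group homologous ORFs across a species panel
#'
#' Each species' ORFs are aligned against every reference protein; an ORF
#' is assigned to (at most) the reference gene it scores best against, and
#' for each gene the best-scoring ORF of each species joins that gene's
#' group. Assignment is independent per species, so the result does not
#' depend on species order.
#'
#' @param orf_sets Named list (species -> list of `mito_orf` from
#'   [scan_orfs()]).
#' @param reference Named character vector of reference proteins, one per
#'   protein-coding gene (see [annotation_proteins()]).
#' @param min_score Minimum raw alignment score for membership (default 50).
#' @param matrix,gap_open,gap_extend Alignment parameters.
#' @return List of `homolog_group` objects: `gene`, `members` (named list
#'   species -> `mito_orf`), `member_scores`, `absent` (species with no
#'   qualifying ORF), `unalignable` (fewer than 2 members); `alignment` and
#'   `column_occupancy` are filled in by [multi_align()].
#' @export
group_homologs <- function(orf_sets, reference, min_score = 50,
                           matrix = blosum62x(), gap_open = 11, gap_extend = 1) {
  genes <- names(reference)
  assign <- list()  # per species: data.frame(orf_idx, gene, score)
  for (sp in names(orf_sets)) {
    orfs <- orf_sets[[sp]]
    if (length(orfs) == 0L) { assign[[sp]] <- NULL; next }
    prot <- vapply(orfs, `[[`, character(1), "protein")
    sc <- vapply(genes, function(g)
      .local_scores(prot, reference[[g]], matrix, gap_open, gap_extend),
      numeric(length(prot)))
    sc <- matrix(sc, nrow = length(prot), dimnames = list(NULL, genes))
    best_gene <- genes[max.col(sc, ties.method = "first")]
    best_score <- sc[cbind(seq_len(nrow(sc)), match(best_gene, genes))]
    keep <- best_score >= min_score
    assign[[sp]] <- data.frame(orf_idx = which(keep), gene = best_gene[keep],
                               score = best_score[keep])
  }
  groups <- lapply(genes, function(g) {
    members <- list(); scores <- numeric(0)
    for (sp in names(orf_sets)) {
      hits <- assign[[sp]]
      hits <- hits[hits$gene == g, , drop = FALSE]
      if (is.null(hits) || nrow(hits) == 0L) next
      # best-scoring ORF wins; break ties towards the longer, then earlier ORF
      cand <- orf_sets[[sp]][hits$orf_idx]
      o <- order(-hits$score,
                 -vapply(cand, `[[`, integer(1), "length_aa"),
                 vapply(cand, `[[`, integer(1), "start"))
      members[[sp]] <- cand[[o[1]]]
      scores[sp] <- hits$score[o[1]]
    }
    structure(list(gene = g, members = members, member_scores = scores,
                   absent = setdiff(names(orf_sets), names(members)),
                   unalignable = length(members) < 2L,
                   alignment = NULL, column_occupancy = NULL),
              class = "homolog_group")
  })
  stats::setNames(groups, genes)
}

#' @export
print.homolog_group <- function(x, ...) {
  cat(sprintf("<homolog_group> %s: %d member(s)%s%s\n", x$gene,
              length(x$members),
              if (x$unalignable) " [unalignable]" else "",
              if (is.null(x$alignment)) "" else
                sprintf(", aligned (%d columns)", nchar(x$alignment[1]))))
  invisible(x)
}

# Full end-gapped rows of an ends-free global alignment of a vs b.
.overlap_align_rows <- function(a, b, matrix, gap_open, gap_extend) {
  pa <- Biostrings::pairwiseAlignment(
    .sanitize_aa(a, matrix), .sanitize_aa(b, matrix), type = "overlap",
    substitutionMatrix = matrix, gapOpening = gap_open, gapExtension = gap_extend)
  mid_a <- as.character(Biostrings::alignedPattern(pa))
  mid_b <- as.character(Biostrings::alignedSubject(pa))
  a1 <- BiocGenerics::start(Biostrings::pattern(pa))
  a2 <- BiocGenerics::end(Biostrings::pattern(pa))
  b1 <- BiocGenerics::start(Biostrings::subject(pa))
  b2 <- BiocGenerics::end(Biostrings::subject(pa))
  gaps <- function(n) strrep("-", n)
  pre_a <- substr(a, 1, a1 - 1); pre_b <- substr(b, 1, b1 - 1)
  suf_a <- substr(a, a2 + 1, nchar(a)); suf_b <- substr(b, b2 + 1, nchar(b))
  row_a <- paste0(pre_a, gaps(nchar(pre_b)), mid_a, suf_a, gaps(nchar(suf_b)))
  row_b <- paste0(gaps(nchar(pre_a)), pre_b, mid_b, gaps(nchar(suf_a)), suf_b)
  c(row_a, row_b)
}

#' Multi-align a homolog group (center star)
#'
#' Deterministic center-star progressive alignment: the member maximizing
#' the summed pairwise ends-free global alignment score is the center;
#' every other member is aligned to the center with free end gaps and the
#' pairwise alignments are merged under "once a gap, always a gap".
#' Reproducible and adequate for the handful of closely related sequences
#' a mitochondrial panel provides.
#'
#' @param group A `homolog_group` with at least 2 members.
#' @param matrix,gap_open,gap_extend Alignment parameters.
#' @return The group with `alignment` (named character vector of equal
#'   length gapped rows) and `column_occupancy` (per-column fraction of
#'   non-gap rows) filled in.
#' @export
multi_align <- function(group, matrix = blosum62x(), gap_open = 11, gap_extend = 1) {
  if (length(group$members) < 2L)
    stop("group '", group$gene, "' has < 2 members and cannot be aligned")
  sp <- names(group$members)
  prot <- vapply(group$members, `[[`, character(1), "protein")
  n <- length(prot)
  ssum <- numeric(n)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    s <- Biostrings::pairwiseAlignment(
      .sanitize_aa(prot[i], matrix), .sanitize_aa(prot[j], matrix),
      type = "overlap", substitutionMatrix = matrix,
      gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
    ssum[i] <- ssum[i] + s; ssum[j] <- ssum[j] + s
  }
  ci <- which.max(ssum)
  center <- prot[ci]
  m <- nchar(center)
  others <- setdiff(seq_len(n), ci)
  pair <- lapply(others, function(j)
    .overlap_align_rows(center, prot[j], matrix, gap_open, gap_extend))
  # master gap counts: gaps_before[i] = gap columns before center residue i,
  # slot m+1 = gaps after the last residue
  gap_counts <- function(center_row) {
    chars <- strsplit(center_row, "")[[1]]
    slots <- integer(m + 1L)
    i <- 1L
    for (ch in chars) {
      if (ch == "-") slots[i] <- slots[i] + 1L else i <- i + 1L
    }
    slots
  }
  per_pair <- lapply(pair, function(p) gap_counts(p[1]))
  master <- Reduce(pmax, per_pair, integer(m + 1L))
  # rebuild rows padded to the master gap pattern
  pad_row <- function(center_row, member_row) {
    cc <- strsplit(center_row, "")[[1]]
    mc <- strsplit(member_row, "")[[1]]
    out <- character(0)
    i <- 1L       # next center residue index
    buf <- character(0)
    flush <- function(buf, slot) c(buf, rep("-", master[slot] - length(buf)))
    k <- 1L
    while (k <= length(cc)) {
      if (cc[k] == "-") buf <- c(buf, mc[k])
      else {
        out <- c(out, flush(buf, i), mc[k])
        buf <- character(0)
        i <- i + 1L
      }
      k <- k + 1L
    }
    out <- c(out, flush(buf, m + 1L))
    paste(out, collapse = "")
  }
  center_master <- {
    res <- strsplit(center, "")[[1]]
    out <- character(0)
    for (i in seq_len(m)) out <- c(out, rep("-", master[i]), res[i])
    paste(c(out, rep("-", master[m + 1L])), collapse = "")
  }
  rows <- stats::setNames(vector("character", n), sp)
  rows[ci] <- center_master
  for (k in seq_along(others))
    rows[others[k]] <- pad_row(pair[[k]][1], pair[[k]][2])
  rowmat <- do.call(rbind, strsplit(rows, ""))
  group$alignment <- rows
  group$column_occupancy <- colMeans(rowmat != "-")
  group
}

# alignment column of each residue of one gapped row
.residue_columns <- function(row) which(strsplit(row, "")[[1]] != "-")

#' Select start codons for every member of an aligned homolog group
#'
#' Operationalizes the cross-species start-selection rule: each candidate
#' start is scored as the number of well-occupied alignment columns (column
#' occupancy at least `occupancy_threshold`) lying at or downstream of the
#' candidate's column, minus `overlap_penalty` per base the candidate
#' overlaps the upstream annotated feature. The maximal-score candidate
#' wins; ties prefer ATG over GTG over TTG, then the most-upstream
#' position. Members with no candidate start are excluded (attribute
#' `no_start`).
#'
#' @param group An aligned `homolog_group` (see [multi_align()]).
#' @param tables Named list (species -> `mito_annotation`), used to locate
#'   the upstream feature and compute intergenic gaps.
#' @param occupancy_threshold Fraction of non-gap rows a column needs to
#'   count as conserved coverage (default 0.5).
#' @param overlap_penalty Score subtracted per base of overlap with the
#'   upstream feature (default 1).
#' @return `data.frame` of start calls: `species`, `gene`, `position`,
#'   `codon`, `upstream_gap` (negative = overlap),
#'   `conserved_columns_covered`, `score`.
#' @export
select_start <- function(group, tables, occupancy_threshold = 0.5,
                         overlap_penalty = 1) {
  if (is.null(group$alignment))
    stop("group must be aligned first (see multi_align)")
  cons <- which(group$column_occupancy >= occupancy_threshold)
  codon_pref <- c(ATG = 1L, GTG = 2L, TTG = 3L)
  calls <- list(); no_start <- character(0)
  for (sp in names(group$members)) {
    orf <- group$members[[sp]]
    cand <- orf$candidate_starts
    if (nrow(cand) == 0L) { no_start <- c(no_start, sp); next }
    tab <- tables[[sp]]
    L <- attr(tab, "genome_length")
    prev_end <- .upstream_feature_end(tab, group$gene, orf$start, L)
    res_cols <- .residue_columns(group$alignment[[sp]])
    cols <- res_cols[cand$codon_index]
    n_cons <- vapply(cols, function(cl) sum(cons >= cl), integer(1))
    gapv <- circular_gap(prev_end, cand$position, L)
    ovl <- pmax(0L, -gapv)
    score <- n_cons - overlap_penalty * ovl
    o <- order(-score,
               codon_pref[cand$codon],
               cand$codon_index)
    pick <- o[1]
    calls[[sp]] <- data.frame(
      species = sp, gene = group$gene,
      position = cand$position[pick], codon = cand$codon[pick],
      upstream_gap = gapv[pick],
      conserved_columns_covered = n_cons[pick],
      score = score[pick])
  }
  out <- do.call(rbind, calls)
  if (!is.null(out)) rownames(out) <- NULL
  attr(out, "no_start") <- no_start
  out
}

# End of the previous gene: the feature immediately before `gene` in
# canonical (start-sorted, circular) order when the gene is annotated,
# else the feature end nearest upstream of `ref_pos`.
.upstream_feature_end <- function(tab, gene, ref_pos, L) {
  others <- tab[tab$gene != gene, , drop = FALSE]
  if (nrow(others) == 0L) return(NA_integer_)
  i <- match(gene, tab$gene)
  if (!is.na(i)) {
    d <- (tab$start[i] - others$start - 1L) %% L
    return(others$end[which.min(d)])
  }
  d <- (ref_pos - others$end - 1L) %% L
  others$end[which.min(d)]
}

#' Refine start codons across a whole panel
#'
#' Convenience wrapper running [scan_orfs()], [group_homologs()],
#' [multi_align()] and [select_start()] over a species panel.
#'
#' @param genomes Named list (species -> `mito_genome`).
#' @param tables Named list (species -> `mito_annotation`).
#' @param reference_species Species whose annotated proteins anchor the
#'   homology groups (default: first species).
#' @param codon_table A [codon_table()].
#' @param min_len Minimum ORF length passed to [scan_orfs()].
#' @param min_score Grouping score threshold.
#' @param occupancy_threshold,overlap_penalty Passed to [select_start()].
#' @return `data.frame` of start calls for every gene and species.
#' @export
refine_starts <- function(genomes, tables,
                          reference_species = names(genomes)[1],
                          codon_table = mitocurate::codon_table(),
                          min_len = 80L, min_score = 50,
                          occupancy_threshold = 0.5, overlap_penalty = 1) {
  orf_sets <- lapply(genomes, scan_orfs, table = codon_table, min_len = min_len)
  reference <- annotation_proteins(genomes[[reference_species]],
                                   tables[[reference_species]], codon_table)
  groups <- group_homologs(orf_sets, reference, min_score = min_score)
  calls <- lapply(groups, function(g) {
    if (g$unalignable) return(NULL)
    g <- multi_align(g)
    select_start(g, tables, occupancy_threshold, overlap_penalty)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
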