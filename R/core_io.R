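#' Construct a circular mitochondrial genome
#'
#' @param sequence Nucleotide string (A/C/G/T/N, case-insensitive).
#' @param id Sequence identifier.
#' @param species Species label; defaults to `id`.
#' @param circular Logical; mitochondrial chromosomes are circular.
#' @return An object of class `mito_genome`.
#' @export
genome <- function(sequence, id, species = id, circular = TRUE) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) < 1L) stop("genome sequence must have length >= 1")
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0L)
    stop("alphabet error: non-ACGTN residue '", substr(sequence, bad, bad),
         "' at position ", bad, " of genome '", id, "'")
  structure(list(id = id, species = species, sequence = sequence,
                 circular = isTRUE(circular)),
            class = "mito_genome")
}

#' @export
print.mito_genome <- function(x, ...) {
  cat("<mito_genome>", x$id, if (!identical(x$species, x$id)) paste0("(", x$species, ")"),
      "-", genome_length(x), "bp,", if (x$circular) "circular" else "linear", "\n")
  invisible(x)
}

#' Genome length in bases
#' @param g A `mito_genome`.
#' @return Integer length.
#' @export
genome_length <- function(g) nchar(g$sequence)

#' Extract a (possibly origin-wrapping) subsequence
#' @param g A `mito_genome`.
#' @param start,end 1-based inclusive positions; `end < start` wraps.
#' @return Nucleotide string.
#' @export
genome_subseq <- function(g, start, end) {
  L <- genome_length(g)
  if (end >= start) return(substr(g$sequence, start, end))
  paste0(substr(g$sequence, start, L), substr(g$sequence, 1L, end))
}

#' Read genomes from a FASTA file
#'
#' @param path FASTA file (multi-record allowed).
#' @return List of `mito_genome`, one per record, in file order. The id is
#'   the first whitespace-delimited token of the header.
#' @export
read_fasta <- function(path) {
  # read as raw strings so alphabet violations are caught (and reported with
  # their position) instead of being silently dropped
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("format error: no FASTA records in ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  out <- vector("list", length(set))
  for (i in seq_along(set)) out[[i]] <- genome(as.character(set[[i]]), ids[i])
  names(out) <- ids
  out
}

#' Write genomes to a FASTA file
#' @param genomes A `mito_genome` or list of them.
#' @param path Output file.
#' @export
write_fasta <- function(genomes, path) {
  if (inherits(genomes, "mito_genome")) genomes <- list(genomes)
  seqs <- Biostrings::DNAStringSet(vapply(genomes, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(genomes, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

.feature_types <- c("CDS", "tRNA", "rRNA", "ncRNA", "ORF")

#' Construct an annotation table
#'
#' Ordered gene features in 1-based inclusive circular coordinates on the
#' sense strand. `end < start` denotes wrap across the origin. Features are
#' sorted by start position; protein-coding gene labels must be unique.
#'
#' @param features `data.frame` with columns `gene`, `type`, `start`, `end`
#'   and optionally `start_codon`.
#' @param genome_id Identifier of the genome the table annotates.
#' @param genome_length Length of that genome.
#' @return A `data.frame` of class `mito_annotation` with attributes
#'   `genome_id` and `genome_length`.
#' @export
annotation_table <- function(features, genome_id, genome_length) {
  req <- c("gene", "type", "start", "end")
  miss <- setdiff(req, names(features))
  if (length(miss)) stop("missing annotation columns: ", paste(miss, collapse = ", "))
  if ("strand" %in% names(features) && any(features$strand != "+"))
    stop("unsupported strand: only '+' features are accepted ",
         "(triclad mitochondrial transcription is single-stranded)")
  tab <- data.frame(
    gene  = as.character(features$gene),
    type  = as.character(features$type),
    start = as.integer(features$start),
    end   = as.integer(features$end),
    strand = "+",
    start_codon = if ("start_codon" %in% names(features))
      as.character(features$start_codon) else NA_character_,
    stringsAsFactors = FALSE
  )
  if (any(!tab$type %in% .feature_types))
    stop("unknown feature type(s): ",
         paste(unique(setdiff(tab$type, .feature_types)), collapse = ", "))
  if (any(tab$start < 1L | tab$start > genome_length |
          tab$end < 1L | tab$end > genome_length))
    stop("validation error: coordinates out of range [1, ", genome_length,
         "] (coordinates are 1-based inclusive)")
  len <- circular_length(tab$start, tab$end, genome_length)
  if (any(len >= genome_length))
    stop("a feature may not cover the full circle")
  cds <- tab$gene[tab$type == "CDS"]
  if (anyDuplicated(cds))
    stop("duplicate protein-coding gene label(s): ",
         paste(unique(cds[duplicated(cds)]), collapse = ", "))
  tab$wraps <- tab$end < tab$start
  tab <- tab[order(tab$start), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, genome_id = genome_id, genome_length = genome_length,
            class = c("mito_annotation", "data.frame"))
}

#' Read an annotation table from TSV
#'
#' Expects a header with columns `gene`, `type`, `start`, `end` (1-based
#' inclusive) and optionally `start_codon` and `strand` (which must be "+").
#'
#' @param path TSV file.
#' @param genome The `mito_genome` the table annotates (coordinates are
#'   validated against its length).
#' @return A `mito_annotation`.
#' @export
read_annotation_table <- function(path, genome) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  annotation_table(df, genome_id = genome$id,
                   genome_length = genome_length(genome))
}

#' Write an annotation table to TSV
#' @param table A `mito_annotation`.
#' @param path Output file.
#' @export
write_annotation_table <- function(table, path) {
  cols <- c("gene", "type", "start", "end", "strand", "start_codon")
  utils::write.table(as.data.frame(table)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an annotation table as GFF3
#'
#' Coordinates are 1-based inclusive on the "+" strand. Origin-wrapping
#' features are split into two lines sharing the same `ID` attribute.
#'
#' @param table A `mito_annotation`.
#' @param path Output file.
#' @export
write_gff <- function(table, path) {
  L <- attr(table, "genome_length")
  gid <- attr(table, "genome_id")
  lines <- c("##gff-version 3",
             paste("##sequence-region", gid, 1L, L))
  for (i in seq_len(nrow(table))) {
    f <- table[i, ]
    attrs <- paste0("ID=", f$gene, ";gene=", f$gene)
    if (!is.na(f$start_codon)) attrs <- paste0(attrs, ";start_codon=", f$start_codon)
    pieces <- circ_pieces(f$start, f$end, L)
    for (j in seq_len(nrow(pieces)))
      lines <- c(lines, paste(gid, "mitocurate", f$type,
                              pieces[j, 1], pieces[j, 2], ".", "+", ".",
                              attrs, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 file written by [write_gff()]
#'
#' Reassembles origin-wrapping features from the two lines sharing an `ID`.
#'
#' @param path GFF3 file.
#' @param genome The annotated `mito_genome`.
#' @return A `mito_annotation`.
#' @export
read_gff <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "gff3")
  L <- genome_length(genome)
  df <- data.frame(
    gene = as.character(gr$ID),
    type = as.character(gr$type),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    start_codon = if (!is.null(gr$start_codon)) as.character(gr$start_codon)
      else NA_character_,
    stringsAsFactors = FALSE
  )
  out <- do.call(rbind, lapply(split(df, df$gene), function(p) {
    if (nrow(p) == 1L) return(p)
    if (nrow(p) != 2L) stop("feature '", p$gene[1], "' split into >2 parts")
    hi <- p[p$end == L, , drop = FALSE]   # part running into the origin
    lo <- p[p$start == 1L, , drop = FALSE]
    if (nrow(hi) != 1L || nrow(lo) != 1L)
      stop("feature '", p$gene[1], "' parts do not abut the origin")
    hi$end <- lo$end
    hi
  }))
  annotation_table(out, genome_id = genome$id, genome_length = L)
}

#' Write intervals as BED6 (0-based, half-open)
#'
#' Origin-wrapping intervals are split into two BED lines sharing a name.
#'
#' @param df `data.frame` with columns `start`, `end` (1-based inclusive)
#'   and optionally `name` and `score`.
#' @param path Output file.
#' @param genome_id Chromosome name for column 1.
#' @param genome_length Circular chromosome length, for wrap splitting.
#' @export
write_bed <- function(df, path, genome_id, genome_length) {
  name <- if ("name" %in% names(df)) as.character(df$name)
    else sprintf("region_%d", seq_len(nrow(df)))
  score <- if ("score" %in% names(df)) df$score else 0
  lines <- character(0)
  for (i in seq_len(nrow(df))) {
    pieces <- circ_pieces(df$start[i], df$end[i], genome_length)
    for (j in seq_len(nrow(pieces)))
      lines <- c(lines, paste(genome_id, pieces[j, 1] - 1L, pieces[j, 2],
                              name[i], score[i], "+", sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
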