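# Hand-built fixtures for unit tests.

# A minimal stand-in ORF for start-selection tests: candidate positions are
# derived from the segment start so genome coordinates stay consistent.
fake_orf <- function(protein, start, candidate_idx, candidate_codons,
                     genome_id = "g", L = 10000L) {
  pos <- ((start - 1L + 3L * (candidate_idx - 1L)) %% L) + 1L
  structure(list(
    genome_id = genome_id, frame = (start - 1L) %% 3L,
    start = start,
    end = ((start - 1L + 3L * nchar(protein) - 1L) %% L) + 1L,
    length_aa = nchar(protein), protein = protein,
    candidate_starts = data.frame(position = pos, codon = candidate_codons,
                                  codon_index = candidate_idx),
    no_stop = FALSE), class = "mito_orf")
}

fake_group <- function(gene, members) {
  structure(list(gene = gene, members = members,
                 member_scores = rep(NA_real_, length(members)),
                 absent = character(0), unalignable = length(members) < 2L,
                 alignment = NULL, column_occupancy = NULL),
            class = "homolog_group")
}

# one-feature-per-row annotation table on a 10 kb toy genome
toy_table <- function(rows, genome_id = "g", L = 10000L) {
  annotation_table(rows, genome_id = genome_id, genome_length = L)
}

# a toy genome of given length with a fixed-seed random sequence
toy_genome <- function(L = 10000L, id = "g", seed = 99L) {
  withr::with_seed(seed, genome(random_dna(L), id = id))
}
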