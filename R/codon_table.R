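#' The echinoderm/flatworm mitochondrial genetic code (table 9)
#'
#' Builds the codon table used throughout: NCBI/ENA translation table 9,
#' which differs from the standard code at AAA (Asn, not Lys), AGA/AGG
#' (Ser, not Arg) and TGA (Trp, not stop); the stop codons are TAA and TAG.
#' The code `"9+TTG"` (the default) extends the initiator set with TTG, the
#' noncanonical start codon inferred for triclad mitochondrial genes;
#' `"9"` keeps the canonical ATG/GTG initiators only.
#'
#' @param code One of `"9+TTG"` or `"9"`.
#' @return An object of class `codon_table`: a list with `code_id`,
#'   `codon_to_aa` (named character vector over all 64 codons, stops as
#'   `"*"`), `stops`, and `start_codons`.
#' @examples
#' ct <- codon_table()
#' ct$codon_to_aa[c("AAA", "AGA", "TGA", "TAA")]  # N S W *
#' @export
codon_table <- function(code = c("9+TTG", "9")) {
  code <- match.arg(code)
  b <- c("T", "C", "A", "G")
  codons <- paste0(rep(b, each = 16), rep(rep(b, each = 4), 4), rep(b, 16))
  std <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",   # TTT..TGG
    "LLLLPPPPHHQQRRRR",   # CTT..CGG
    "IIIMTTTTNNKKSSRR",   # ATT..AGG
    "VVVVAAAADDEEGGGG"    # GTT..GGG
  ), "")[[1]]
  aa <- stats::setNames(std, codons)
  aa[c("AAA", "AGA", "AGG", "TGA")] <- c("N", "S", "S", "W")
  starts <- if (code == "9+TTG") c("ATG", "GTG", "TTG") else c("ATG", "GTG")
  out <- structure(list(code_id = code, codon_to_aa = aa,
                        stops = names(aa)[aa == "*"], start_codons = starts),
                   class = "codon_table")
  stopifnot(length(out$codon_to_aa) == 64L, length(out$stops) > 0L,
            !any(out$start_codons %in% out$stops))
  out
}

#' Translate a nucleotide sequence
#'
#' Codon-by-codon translation under a [codon_table()]. Stop codons are
#' rendered `"*"` and do not terminate translation (the caller decides what
#' a stop means). Codons containing a residue outside ACGT translate to
#' `"X"`. A trailing partial codon is dropped with a warning.
#'
#' @param seq Nucleotide string.
#' @param table A `codon_table`.
#' @param as_initiator If `TRUE`, the first codon is rendered `"M"` when it
#'   is in the table's initiator set (initiator codons are read as
#'   formyl-Met regardless of their elongation meaning).
#' @return Amino-acid string.
#' @examples
#' translate("ATGAAAAGATGA", codon_table())           # "MNSW"
#' translate("TTGGCT", codon_table(), as_initiator = TRUE)  # "MA"
#' @export
translate <- function(seq, table = codon_table(), as_initiator = FALSE) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (n == 0L) return("")
  if (n %% 3L != 0L) {
    warning("sequence length not divisible by 3; dropping trailing partial codon")
    n <- n - n %% 3L
    seq <- substr(seq, 1L, n)
  }
  at <- seq.int(1L, n, by = 3L)
  codons <- substring(seq, at, at + 2L)
  aa <- unname(table$codon_to_aa[codons])
  aa[is.na(aa)] <- "X"
  if (as_initiator && codons[1] %in% table$start_codons) aa[1] <- "M"
  paste(aa, collapse = "")
}
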