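# Codon universe used across the package. DNA alphabet internally; RNA
# input (U) is accepted at the boundaries and normalized with rna_to_dna().

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Sense codons (DNA alphabet)
#'
#' The 61 sense codons of the standard genetic code, DNA alphabet,
#' in a fixed order used by all per-codon tables in the package.
#'
#' @return Character vector of length 61.
#' @export
sense_codons <- function() {
  cods <- sort(names(Biostrings::GENETIC_CODE))
  setdiff(cods, STOP_CODONS)
}

#' Translate a codon to its amino acid
#' @param codon character vector of codons (DNA or RNA alphabet).
#' @return One-letter amino-acid codes ("*" for stops).
#' @export
codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[rna_to_dna(codon)])
}

#' Convert RNA-style codons/anticodons to the internal DNA alphabet
#' @param x character vector.
#' @return `x` uppercased with U replaced by T.
#' @export
rna_to_dna <- function(x) {
  chartr("Uu", "TT", toupper(x))
}

#' Convert DNA-style codons to RNA display form
#' @param x character vector.
#' @return `x` with T replaced by U.
#' @export
dna_to_rna <- function(x) {
  chartr("T", "U", toupper(x))
}

# reverse complement for plain character vectors of short sequences
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# codon counts per sequence: named matrix (rows = seqs) over all 64 codons,
# read in-frame from position 1
codon_count_matrix <- function(seqs) {
  dss <- Biostrings::DNAStringSet(seqs)
  m <- Biostrings::trinucleotideFrequency(dss, step = 3)
  m[, , drop = FALSE]
}
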