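# Genetic-code constants shared across the package. DNA alphabet throughout;
# mRNA-style input (U) is normalised to T at the IO boundary.

#' @importFrom Biostrings GENETIC_CODE
NULL

codon_to_aa <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

#' Stop codons of the standard genetic code
#' @keywords internal
stop_codons <- c("TAA", "TAG", "TGA")

#' The 61 sense codons, in genetic-code order
#' @keywords internal
sense_codons <- names(codon_to_aa)[codon_to_aa != "*"]

aa_to_codons <- split(sense_codons, codon_to_aa[sense_codons])

# Canonical Start plus the common near-cognate alternative Start codons;
# these are fast under RRT and depleted in 5' leaders.
start_like_codons <- c("ATG", "ATT", "TTG", "ATA")

#' Translate a codon vector to a one-letter amino-acid string
#'
#' Standard genetic code; a trailing stop codon translates to `"*"`.
#'
#' @param codons character vector of 3-letter DNA codons.
#' @return single string of one-letter amino-acid codes.
#' @export
translate_codons <- function(codons) {
  aa <- codon_to_aa[codons]
  if (anyNA(aa)) {
    stop("unknown codon(s): ", paste(unique(codons[is.na(aa)]), collapse = ", "))
  }
  paste(aa, collapse = "")
}

# Split an in-frame nucleotide string into codons. Assumes nchar %% 3 == 0.
split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

normalize_codon <- function(x) {
  gsub("U", "T", toupper(x), fixed = TRUE)
}
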