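#' @useDynLib placeprof, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Canonical residue order used throughout the likelihood machinery.
# This matches the row/column order of the shipped exchangeability matrices.
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Encode an amino-acid string as integer states
#'
#' Residues outside the 20 canonical amino acids (gaps, `X`, `*`, ambiguity
#' codes) are encoded as `NA` and treated as missing data by the likelihood
#' functions.
#'
#' @param aa character scalar, amino-acid sequence.
#' @return integer vector of states in `1..20`, `NA` for non-canonical symbols.
#' @keywords internal
encode_aa <- function(aa) {
  match(strsplit(toupper(aa), "")[[1]], AA_ALPHABET)
}

decode_aa <- function(states, missing_char = "-") {
  out <- AA_ALPHABET[states]
  out[is.na(states)] <- missing_char
  paste(out, collapse = "")
}

#' Reverse complement of a DNA string
#' @param dna character scalar over `ACGTN` (case-insensitive).
#' @return character scalar.
#' @export
revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

# Deterministic log-sum-exp along rows of a matrix (or of a vector).
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
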