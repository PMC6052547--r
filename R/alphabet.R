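# Fixed residue ordering used by every matrix in the package:
# alphabetical one-letter amino-acid codes. Column j of any profile is the
# probability of AA_ALPHABET[j]. Integer codes are 1..20 in this order; code
# 21 is the padding symbol with an all-zero embedding row.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

PAD_CODE <- 21L

#' The amino-acid alphabet used throughout the package
#'
#' All profile matrices order their 20 columns by this vector (alphabetical
#' one-letter codes), and all sequence encodings use the matching integer
#' codes 1..20.
#'
#' @return Character vector of the 20 canonical amino-acid one-letter codes.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() AA_ALPHABET

# residues: single string -> integer vector of codes 1..20
encode_residues <- function(residues) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  idx <- match(chars, AA_ALPHABET)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    abort(sprintf("non-canonical residue character(s): %s",
                  paste(bad, collapse = ", ")))
  }
  idx
}

decode_residues <- function(codes) paste(AA_ALPHABET[codes], collapse = "")
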