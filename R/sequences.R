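#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a tibble of sequences. The identifier of each
#' record is the header token before the first whitespace; residues are
#' upper-cased but not otherwise altered, so irregular characters survive and
#' can be screened later with [validate_training_sequence()].
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (character), `residues` (character,
#'   upper case) and `length` (integer), one row per record in file order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">q1 some description", "ACDEFG", ">q2", "MKV", "LAW"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) > 0L) {
    first <- nonblank[1L]
    if (!startsWith(trimws(lines[first]), ">")) {
      abort(sprintf("malformed FASTA: sequence data before any header at line %d",
                    first))
    }
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1L)
  residues <- toupper(as.character(set))
  tibble(id = unname(ids),
         residues = unname(residues),
         length = nchar(unname(residues)))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Tibble with columns `id` and `residues`, as from [read_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  out <- character(2L * nrow(seqs))
  out[c(TRUE, FALSE)] <- paste0(">", seqs$id)
  out[c(FALSE, TRUE)] <- seqs$residues
  writeLines(out, path)
  invisible(path)
}

#' Screen sequences for training eligibility
#'
#' A sequence qualifies for training when it contains only the 20 canonical
#' amino-acid letters — irregular characters such as B, Z, J, U, O or X
#' disqualify it — and its length lies in 50..1000.
#'
#' @param residues Character vector of residue strings (upper case).
#' @param min_len,max_len Inclusive length bounds; defaults 50 and 1000.
#' @return Logical vector, one entry per input string.
#' @export
#' @examples
#' validate_training_sequence(c(strrep("ACDEFGHIKL", 6), "ACDXE"))
validate_training_sequence <- function(residues, min_len = 50L, max_len = 1000L) {
  n <- nchar(residues)
  canonical <- grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"),
                     residues)
  canonical & n >= min_len & n <= max_len
}
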