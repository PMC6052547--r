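#' Parse an HHM-format profile HMM
#'
#' Reads the match states of a text profile HMM in the HHM layout: after the
#' `HMM` header line (whose tokens give the amino-acid column order), each
#' match state is a line whose first token is the consensus residue letter and
#' second token the 1-based state index, followed by 20 emission scores.
#' Scores are integers equal to `-1000 * log2(p)`; `*` means probability 0.
#' Decoded rows are renormalized to sum to 1. Interleaved transition lines and
#' the `NULL` background line are skipped; `//` ends the model.
#'
#' @param path Path to an HHM file.
#' @return An object of class `hhm_profile`: list with `match_states` (M x 20
#'   matrix of emission frequencies, columns in [aa_alphabet()] order), `name`
#'   (from the `NAME` line, or `""`) and `consensus` (character string of the
#'   match-state residue letters).
#' @export
#' @examples
#' hhm <- parse_hhm(system.file("extdata", "example_synthetic.hhm",
#'                              package = "seqprof"))
#' hhm
#' rowSums(hhm$match_states)
parse_hhm <- function(path) {
  if (!file.exists(path)) abort(sprintf("HHM file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  name <- ""
  nm <- grep("^NAME\\s", lines)
  if (length(nm) > 0L)
    name <- sub("^NAME\\s+", "", lines[nm[1L]])

  hdr <- grep("^HMM\\s", lines)
  if (length(hdr) == 0L) abort("malformed HHM: no 'HMM' header line")
  hdr <- hdr[1L]
  order_tokens <- strsplit(trimws(lines[hdr]), "\\s+")[[1L]][-1L]
  col_map <- match(AA_ALPHABET, order_tokens)
  if (anyNA(col_map))
    abort("malformed HHM: header does not list all 20 amino acids")

  rows <- list()
  consensus <- character()
  state_pat <- "^[ACDEFGHIKLMNPQRSTVWYX-]\\s+[0-9]+\\s"
  i <- hdr + 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "//")) break
    if (grepl(state_pat, ln)) {
      tok <- strsplit(trimws(ln), "\\s+")[[1L]]
      state <- length(rows) + 1L
      if (length(tok) < 22L)
        abort(sprintf("malformed HHM: match state %d has fewer than 20 scores",
                      state))
      scores <- tok[3:22]
      p <- ifelse(scores == "*", 0, 2^(-suppressWarnings(as.numeric(scores)) / 1000))
      if (anyNA(p))
        abort(sprintf("malformed HHM: non-numeric score in match state %d", state))
      if (sum(p) <= 0)
        abort(sprintf("malformed HHM: all-zero emissions in match state %d", state))
      rows[[state]] <- (p / sum(p))[col_map]
      consensus <- c(consensus, tok[1L])
    }
    i <- i + 1L
  }
  if (length(rows) == 0L) abort("malformed HHM: no match states found")
  m <- do.call(rbind, rows)
  colnames(m) <- AA_ALPHABET
  structure(list(match_states = m, name = name,
                 consensus = paste(consensus, collapse = "")),
            class = "hhm_profile")
}

#' @export
print.hhm_profile <- function(x, ...) {
  cat(sprintf("<hhm_profile> '%s': %d match states\n", x$name,
              nrow(x$match_states)))
  invisible(x)
}

#' Convert a profile HMM to a PSSM
#'
#' The PSSM is obtained by extracting the amino-acid emission frequencies of
#' the match states: one profile row per match state, unchanged.
#'
#' @param hmm An `hhm_profile` from [parse_hhm()].
#' @return A [profile_matrix()] with `source = "converted"`.
#' @export
hmm_to_pssm <- function(hmm) {
  if (!inherits(hmm, "hhm_profile")) abort("`hmm` must be an hhm_profile")
  if (nrow(hmm$match_states) == 0L) abort("profile HMM has no match states")
  profile_matrix(hmm$match_states, source = "converted", tol = 1e-4)
}
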