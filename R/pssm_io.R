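#' Default background amino-acid frequencies
#'
#' The package ships a uniform background (0.05 per residue type) for log-odds
#' display; any strictly positive probability vector can be supplied instead.
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
uniform_background <- function() setNames(rep(1 / 20, 20L), AA_ALPHABET)

#' Write a profile to the ASCII PSSM dialect
#'
#' The file carries two blocks. A display block modeled on PSI-BLAST ASCII
#' PSSMs gives, per site: the 1-based position, the consensus residue
#' (argmax), 20 half-bit log-odds scores `round(2 * log2(p / q))` with `p`
#' clamped to at least `1e-4`, and the 20 frequencies as percentages. A
#' lossless block then repeats every frequency at full precision so
#' [read_pssm()] reproduces the profile within 1e-9; the lossless block is
#' authoritative.
#'
#' @param p A [profile_matrix()].
#' @param path Output path.
#' @param background Strictly positive probability vector of length 20 in
#'   [aa_alphabet()] order; defaults to [uniform_background()].
#' @return `path`, invisibly.
#' @export
#' @examples
#' prof <- profile_matrix(matrix(1 / 20, 3, 20), source = "teacher")
#' f <- tempfile(fileext = ".pssm")
#' write_pssm(prof, f)
#' max(abs(read_pssm(f) - prof))
write_pssm <- function(p, path, background = uniform_background()) {
  if (!is_profile_matrix(p)) p <- profile_matrix(p, source = "predicted")
  background <- as.numeric(background)
  if (length(background) != 20L) abort("background must have 20 entries")
  if (any(background <= 0)) abort("background frequencies must be strictly positive")
  background <- background / sum(background)

  n <- nrow(p)
  clamped <- pmax(unclass(p), 1e-4)
  lodds <- round(2 * log2(sweep(clamped, 2L, background, "/")))
  cons <- AA_ALPHABET[max.col(unclass(p), ties.method = "first")]

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# seqprof PSSM v1",
    sprintf("# sites: %d", n),
    sprintf("# alphabet: %s", paste(AA_ALPHABET, collapse = "")),
    sprintf("# source: %s", attr(p, "source") %||% "predicted"),
    sprintf("# background: %s", paste(sprintf("%.17g", background), collapse = " ")),
    sprintf("# pos cons %s | %s (freq %%)",
            paste(AA_ALPHABET, collapse = " "), paste(AA_ALPHABET, collapse = " "))
  ), con)
  for (t in seq_len(n)) {
    writeLines(sprintf("%d %s %s | %s", t, cons[t],
                       paste(sprintf("%d", lodds[t, ]), collapse = " "),
                       paste(sprintf("%.1f", 100 * p[t, ]), collapse = " ")), con)
  }
  writeLines("# frequencies", con)
  for (t in seq_len(n)) {
    writeLines(sprintf("%d %s", t,
                       paste(sprintf("%.17g", p[t, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a profile from the ASCII PSSM dialect
#'
#' Reads the lossless frequency block written by [write_pssm()]; files lacking
#' it are rejected.
#'
#' @param path Path to a file written by [write_pssm()].
#' @return A [profile_matrix()]; its `source` attribute and `background`
#'   attribute are restored from the header.
#' @export
read_pssm <- function(path) {
  if (!file.exists(path)) abort(sprintf("PSSM file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || lines[1L] != "# seqprof PSSM v1")
    abort("not a seqprof PSSM file (missing version header)")
  src <- sub("^# source: ", "", grep("^# source: ", lines, value = TRUE)[1L])
  bg_line <- grep("^# background: ", lines, value = TRUE)[1L]
  background <- as.numeric(strsplit(sub("^# background: ", "", bg_line), " ")[[1L]])
  start <- match("# frequencies", lines)
  if (is.na(start))
    abort("PSSM file lacks the lossless frequency block")
  rows <- lines[(start + 1L):length(lines)]
  rows <- rows[nzchar(trimws(rows))]
  vals <- lapply(strsplit(trimws(rows), "\\s+"), function(tok) {
    as.numeric(tok[-1L])
  })
  m <- do.call(rbind, vals)
  if (ncol(m) != 20L) abort("malformed lossless frequency block")
  out <- profile_matrix(m, source = if (src %in% c("teacher", "predicted", "converted"))
    src else "predicted")
  attr(out, "background") <- background
  out
}
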