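#' Construct a profile matrix (PSSM in frequency form)
#'
#' A profile matrix holds one 20-dimensional amino-acid probability column per
#' sequence position: row `t`, column `j` is the probability of residue
#' `aa_alphabet()[j]` at site `t`. Rows must be probability vectors.
#'
#' @param x Numeric matrix with 20 columns; rows are sites.
#' @param source One of `"teacher"`, `"predicted"`, `"converted"` — where the
#'   profile came from.
#' @param tol Row-sum tolerance (default `1e-6`).
#' @return The validated matrix with class `profile_matrix` and a `source`
#'   attribute; column names are the alphabet.
#' @export
profile_matrix <- function(x, source = c("teacher", "predicted", "converted"),
                           tol = 1e-6) {
  source <- match.arg(source)
  x <- as.matrix(x)
  if (ncol(x) != 20L) abort("a profile matrix must have exactly 20 columns")
  if (nrow(x) < 1L) abort("a profile matrix must have at least one row")
  if (any(!is.finite(x)) || any(x < -tol) || any(x > 1 + tol))
    abort("profile entries must be probabilities in [0, 1]")
  if (any(abs(rowSums(x) - 1) > tol))
    abort(sprintf("profile rows must sum to 1 within %g", tol))
  dimnames(x) <- list(NULL, AA_ALPHABET)
  structure(x, class = c("profile_matrix", class(x)), source = source)
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %d sites x 20 residues (source: %s)\n",
              nrow(x), attr(x, "source")))
  print(utils::head(round(unclass(x), 3), 5L))
  if (nrow(x) > 5L) cat(sprintf("... %d more sites\n", nrow(x) - 5L))
  invisible(x)
}

is_profile_matrix <- function(x) inherits(x, "profile_matrix")
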