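# model list -> argument list for the C++ kernels
model_par <- function(model) {
  model[c("embed", "Wx", "Wh", "b", "Wy", "by")]
}

#' Embed a residue symbol
#'
#' Looks up the word-embedding row of a residue; the padding symbol `"-"`
#' maps to the all-zero row.
#'
#' @param model A `seqprof_model`.
#' @param residue Single character: one of [aa_alphabet()] or `"-"` (padding).
#' @return Numeric vector of length `d`.
#' @export
embed_residue <- function(model, residue) {
  if (identical(residue, "-")) return(model$embed[PAD_CODE, ])
  idx <- match(residue, AA_ALPHABET)
  if (is.na(idx)) abort(sprintf("unknown residue symbol '%s'", residue))
  model$embed[idx, ]
}

#' One LSTM step
#'
#' Advances the recurrent state by one position. With input `u`, hidden state
#' `h` and memory cell `c`:
#' \deqn{i = \sigma(u W_i + h R_i + b_i), \quad f = \sigma(u W_f + h R_f + b_f),}
#' \deqn{z = \tanh(u W_z + h R_z + b_z), \quad o = \sigma(u W_o + h R_o + b_o),}
#' \deqn{c' = f \circ c + i \circ z, \qquad v = o \circ \tanh(c'), \qquad h' = v.}
#'
#' @param model A `seqprof_model` (its LSTM block is used).
#' @param u Numeric input vector of length `d`.
#' @param state List with `hidden` and `cell` (each length `H`), or `NULL`
#'   for the null (all-zero) state.
#' @return List with `v` (the unit output) and `state` (list `hidden`,
#'   `cell`).
#' @export
lstm_step <- function(model, u, state = NULL) {
  d <- model$dims$d; H <- model$dims$H
  if (length(u) != d) abort("input vector has wrong length")
  if (is.null(state)) state <- list(hidden = rep(0, H), cell = rep(0, H))
  if (length(state$hidden) != H || length(state$cell) != H)
    abort("state vectors have wrong length")
  a <- as.numeric(u %*% model$Wx) + as.numeric(state$hidden %*% model$Wh) + model$b
  sig <- function(x) 1 / (1 + exp(-x))
  i <- sig(a[1:H])
  f <- sig(a[(H + 1):(2 * H)])
  z <- tanh(a[(2 * H + 1):(3 * H)])
  o <- sig(a[(3 * H + 1):(4 * H)])
  cell <- f * state$cell + i * z
  v <- o * tanh(cell)
  list(v = v, state = list(hidden = v, cell = cell))
}

#' Generate a profile for one sequence
#'
#' Runs the network left to right from the null state and emits one softmax
#' probability column per site: row `t` is
#' `softmax(v_t %*% Wy + by)` where `v_t` is the LSTM output after consuming
#' residues `1..t`.
#'
#' @param model A `seqprof_model`.
#' @param residues Residue string over [aa_alphabet()].
#' @return A [profile_matrix()] (`source = "predicted"`) with an integer
#'   attribute `steps` counting LSTM step invocations (always the sequence
#'   length: the generator is O(N)).
#' @export
#' @examples
#' m <- init_profiler(d = 4, H = 8, seed = 1)
#' p <- forward_profile(m, "ACDEFGHIKL")
#' rowSums(p)
forward_profile <- function(model, residues) {
  codes <- encode_residues(residues)
  if (length(codes) == 0L) abort("empty sequence")
  out <- cpp_forward(codes, model_par(model))
  p <- profile_matrix(out$profile, source = "predicted", tol = 1e-9)
  attr(p, "steps") <- out$steps
  p
}

#' Generate a profile with truncated memory
#'
#' Memory-reset prediction: row `t` is produced by running the network from
#' the null state over the window `max(1, t - L + 1)..t`, so each site sees at
#' most `L` sites of context including itself. `L >= N` reproduces
#' [forward_profile()] exactly.
#'
#' @param model A `seqprof_model`.
#' @param residues Residue string.
#' @param L Memory reset length (positive integer).
#' @return A [profile_matrix()] with attribute `steps` (total LSTM step
#'   invocations, at most `N * L`).
#' @export
truncated_forward <- function(model, residues, L) {
  if (length(L) != 1L || !is.finite(L) || L < 1) abort("L must be >= 1")
  codes <- encode_residues(residues)
  if (length(codes) == 0L) abort("empty sequence")
  out <- cpp_truncated_forward(codes, model_par(model), as.integer(min(L, length(codes))))
  p <- profile_matrix(out$profile, source = "predicted", tol = 1e-9)
  attr(p, "steps") <- out$steps
  p
}
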