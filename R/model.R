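#' Initialize profile-generator network parameters
#'
#' The generator is: residue -> word embedding (`d` dims) -> single LSTM layer
#' with input, forget and output gates and a constant-error memory cell (`H`
#' units per gate) -> fully connected layer -> softmax over the 20 residue
#' types. The embedding table has 21 rows: the 20 residues plus a padding
#' symbol whose row is fixed at zero.
#'
#' Weights are drawn from scaled normal distributions (sd `1/sqrt(fan-in)`,
#' embedding sd 0.5); biases start at zero except the forget-gate bias
#' (`forget_bias`, default 2), which starts positive so early training does
#' not flush the memory cell — the standard remedy for vanishing memory in
#' forget-gate LSTMs, and the stronger setting measurably speeds the
#' formation of long-range memory.
#'
#' The reference configuration of the method is `d = 400`, `H = 3200`;
#' scaled-down configurations are valid everywhere in the package.
#'
#' @param d Embedding dimension.
#' @param H LSTM unit size (per gate).
#' @param seed Integer seed for the parameter draw.
#' @param forget_bias Initial forget-gate bias (default 2).
#' @return An object of class `seqprof_model`.
#' @export
init_profiler <- function(d = 16L, H = 64L, seed = 1L, forget_bias = 2) {
  if (d < 1L || H < 1L) abort("d and H must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  embed <- matrix(stats::rnorm(21L * d, sd = 0.5), 21L, d)
  embed[PAD_CODE, ] <- 0
  b <- rep(0, 4L * H)
  b[(H + 1L):(2L * H)] <- forget_bias  # forget gate open at start
  model <- list(
    embed = embed,
    Wx = matrix(stats::rnorm(d * 4L * H, sd = 1 / sqrt(d)), d, 4L * H),
    Wh = matrix(stats::rnorm(H * 4L * H, sd = 1 / sqrt(H)), H, 4L * H),
    b = b,
    Wy = matrix(stats::rnorm(H * 20L, sd = 1 / sqrt(H)), H, 20L),
    by = rep(0, 20L),
    dims = list(d = as.integer(d), H = as.integer(H))
  )
  structure(model, class = "seqprof_model")
}

#' @export
print.seqprof_model <- function(x, ...) {
  n_par <- sum(vapply(x[c("embed", "Wx", "Wh", "b", "Wy", "by")], length, 1L))
  cat(sprintf("<seqprof_model> d = %d, H = %d (%s parameters)\n",
              x$dims$d, x$dims$H, format(n_par, big.mark = ",")))
  invisible(x)
}

# save/restore .Random.seed so seeded constructors do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Extract the parameters of one LSTM gate
#'
#' The model stores the four gates' weights column-concatenated; this accessor
#' returns one gate's input weights `W` (d x H), recurrent weights `R`
#' (H x H) and bias `b` (length H).
#'
#' @param model A `seqprof_model`.
#' @param gate One of `"input"`, `"forget"`, `"candidate"`, `"output"`.
#' @return List with elements `W`, `R`, `b`.
#' @export
lstm_gate_params <- function(model,
                             gate = c("input", "forget", "candidate", "output")) {
  gate <- match.arg(gate)
  H <- model$dims$H
  k <- match(gate, c("input", "forget", "candidate", "output"))
  cols <- ((k - 1L) * H + 1L):(k * H)
  list(W = model$Wx[, cols, drop = FALSE],
       R = model$Wh[, cols, drop = FALSE],
       b = model$b[cols])
}

#' Save / load a model container
#'
#' Models serialize to a single versioned container file.
#'
#' @param model A `seqprof_model`.
#' @param path File path.
#' @return `write_model()` returns `path` invisibly; `read_model()` returns
#'   the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "seqprof_model"))
  saveRDS(list(format = "seqprof_model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "seqprof_model"))
    abort("not a seqprof model container")
  obj$model
}
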