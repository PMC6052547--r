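#' Configuration of the synthetic profile teacher
#'
#' The teacher is a known context-dependent ground truth mapping sequence
#' context to 20-dimensional profile columns — a controlled stand-in for
#' profiles computed by iterative database search. Each site `t` is assigned a
#' hidden environment state by hashing the `context_k` residues immediately
#' before `t`; in long-range mode (`pair_offset` set) the state additionally
#' depends on the residue at `t - pair_offset`, emulating the remote pairing
#' of beta-strand partners. Each state owns a fixed profile column drawn from
#' a Dirichlet distribution; the target row at a site is its state's column,
#' and the residue at the site is sampled from that row.
#'
#' Sites whose local context window extends before position 1 draw on hidden
#' "burn-in" residues sampled per sequence and never revealed: the first
#' `context_k` sites of a sequence are therefore genuinely ambiguous to any
#' causal predictor, the synthetic analogue of a real protein segment whose
#' upstream context the null initial network state cannot encode. The
#' long-range pairing term, by contrast, is simply inactive at sites
#' `t <= pair_offset` (the partner residue does not exist), as for the first
#' strand of a beta pair.
#'
#' With `rho > 0` the state persists from the previous site whenever a
#' deterministic hash of the previous residue falls below `rho`, creating
#' longer same-state runs while keeping the assignment a pure function of the
#' residues emitted so far. The default `rho = 0` keeps the Bayes-optimal
#' predictor exactly recoverable.
#'
#' @param n_states Number of hidden environment states (default 4).
#' @param context_k Local context length: the state at `t` depends on residues
#'   `t - context_k .. t - 1` (default 2). `context_k = 0` with no
#'   `pair_offset` is the context-free limit (every site shares one column).
#' @param pair_offset Optional positive integer: long-range mode, state at `t`
#'   additionally depends on the residue at `t - pair_offset`.
#' @param rho Markov persistence probability in `[0, 1)` (default 0).
#' @param alpha Dirichlet concentration for drawing state columns (default
#'   0.2: peaked, well-separated columns, as in conserved profile positions).
#' @param length_range Integer two-vector, uniform sequence length range
#'   (default `c(50, 100)`).
#' @param seed Integer seed for the state-column draw.
#' @return A `teacher_config` list.
#' @export
teacher_config <- function(n_states = 4L, context_k = 2L, pair_offset = NULL,
                           rho = 0, alpha = 0.2, length_range = c(50L, 100L),
                           seed = 1L) {
  if (n_states < 1L) abort("n_states must be >= 1")
  if (context_k < 0L || context_k > 8L)
    abort("context_k must be in 0..8")
  if (!is.null(pair_offset) && pair_offset < 1L)
    abort("pair_offset must be a positive integer")
  if (rho < 0 || rho >= 1) abort("rho must be in [0, 1)")
  if (length(length_range) != 2L || length_range[1L] > length_range[2L] ||
      length_range[1L] < 1L)
    abort("length_range must be c(min, max) with 1 <= min <= max")
  structure(list(n_states = as.integer(n_states),
                 context_k = as.integer(context_k),
                 pair_offset = if (is.null(pair_offset)) NULL else as.integer(pair_offset),
                 rho = rho, alpha = alpha,
                 length_range = as.integer(length_range),
                 seed = as.integer(seed)),
            class = "teacher_config")
}

# multipliers for the rolling context hash (distinct odd primes)
.context_weights <- c(7L, 31L, 131L, 509L, 1021L, 2053L, 4099L, 8209L)

#' Build a synthetic teacher
#'
#' Draws the per-state profile columns from `Dirichlet(alpha)` under the
#' config seed and fixes the deterministic environment-assignment rule.
#'
#' @param config A [teacher_config()].
#' @return An object of class `seqprof_teacher` with fields `columns`
#'   (`n_states` x 20 matrix of probability rows) and `config`.
#' @export
make_teacher <- function(config = teacher_config()) {
  stopifnot(inherits(config, "teacher_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  g <- matrix(rgamma(config$n_states * 20L, shape = config$alpha, rate = 1),
              config$n_states, 20L)
  # guard against an all-zero row at tiny alpha
  g[rowSums(g) == 0, 1L] <- 1
  cols <- g / rowSums(g)
  colnames(cols) <- AA_ALPHABET
  structure(list(columns = cols, config = config), class = "seqprof_teacher")
}

#' @export
print.seqprof_teacher <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<seqprof_teacher> %d states, context_k = %d%s, rho = %g, alpha = %g\n",
    cfg$n_states, cfg$context_k,
    if (is.null(cfg$pair_offset)) "" else sprintf(", pair_offset = %d", cfg$pair_offset),
    cfg$rho, cfg$alpha))
  invisible(x)
}

# number of hidden residues prefixed to every sequence so each visible site
# has a complete local context window; the long-range pairing term is only
# active once its partner site actually exists
teacher_burn_in <- function(config) {
  config$context_k
}

# Environment states for an extended residue code vector (burn-in + visible).
# Pure function of the codes; returns states (0-based) for the visible part.
teacher_states <- function(teacher, codes_ext) {
  cfg <- teacher$config
  burn <- teacher_burn_in(cfg)
  n_vis <- length(codes_ext) - burn
  k <- cfg$context_k
  ns <- cfg$n_states
  w <- .context_weights[seq_len(max(k, 1L))]
  states <- integer(n_vis)
  prev <- 0L
  for (t in seq_len(n_vis)) {
    p <- t + burn
    s <- 0L
    if (k > 0L) {
      ctx <- codes_ext[(p - k):(p - 1L)]
      s <- sum(ctx * w[seq_len(k)]) %% ns
    }
    if (!is.null(cfg$pair_offset) && t - cfg$pair_offset >= 1L) {
      s <- (s + codes_ext[p - cfg$pair_offset]) %% ns
    }
    if (cfg$rho > 0 && p > 1L) {
      # persistence decided by a deterministic hash of the previous residue
      if (((codes_ext[p - 1L] * 2654435761) %% 1000) < 1000 * cfg$rho) s <- prev
    }
    states[t] <- s
    prev <- s
  }
  states
}

#' Teacher-truth profile for a given residue string
#'
#' Returns the exact target matrix the teacher assigns to `residues`, given a
#' (hidden) burn-in prefix. Useful for perturbation experiments: changing one
#' visible residue changes exactly the target rows whose context window covers
#' it.
#'
#' @param teacher A `seqprof_teacher`.
#' @param residues Visible residue string.
#' @param burn_in_residues Optional residue string of length `context_k`
#'   supplying the hidden prefix; defaults to all-alanine (deterministic).
#' @return A [profile_matrix()] (`source = "teacher"`).
#' @export
teacher_profile <- function(teacher, residues, burn_in_residues = NULL) {
  cfg <- teacher$config
  burn <- teacher_burn_in(cfg)
  if (is.null(burn_in_residues)) burn_in_residues <- strrep("A", burn)
  if (nchar(burn_in_residues) != burn)
    abort(sprintf("burn_in_residues must have %d residues", burn))
  codes_ext <- c(if (burn > 0L) encode_residues(burn_in_residues),
                 encode_residues(residues))
  st <- teacher_states(teacher, codes_ext)
  profile_matrix(teacher$columns[st + 1L, , drop = FALSE], source = "teacher")
}

#' Sample one (sequence, profile) training pair
#'
#' Iterates sites left to right: the environment state is computed from the
#' residues already emitted (plus the hidden burn-in prefix), the target row
#' is that state's column, and the residue is sampled from the target row.
#' The returned profile is the exact teacher truth, not the empirical draw.
#'
#' @param teacher A `seqprof_teacher`.
#' @param length Sequence length `N >= 1`.
#' @param id Identifier for the pair.
#' @return List with `id`, `residues` (string of length `N`), `profile`
#'   (N x 20 [profile_matrix()]), `states` (integer vector of the hidden
#'   environment states, 0-based) and `burn_in` (the hidden prefix residues —
#'   diagnostic only, never an input to training).
#' @export
sample_pair <- function(teacher, length, id = "synthetic") {
  if (length < 1L) abort("length must be >= 1")
  cfg <- teacher$config
  burn <- teacher_burn_in(cfg)
  n_ext <- burn + length
  codes <- integer(n_ext)
  if (burn > 0L) codes[seq_len(burn)] <- sample.int(20L, burn, replace = TRUE)
  states <- integer(length)
  target <- matrix(0, length, 20L)
  k <- cfg$context_k
  ns <- cfg$n_states
  w <- .context_weights[seq_len(max(k, 1L))]
  prev <- 0L
  for (t in seq_len(length)) {
    p <- t + burn
    s <- 0L
    if (k > 0L) {
      ctx <- codes[(p - k):(p - 1L)]
      s <- sum(ctx * w[seq_len(k)]) %% ns
    }
    if (!is.null(cfg$pair_offset) && t - cfg$pair_offset >= 1L)
      s <- (s + codes[p - cfg$pair_offset]) %% ns
    if (cfg$rho > 0 && p > 1L) {
      if (((codes[p - 1L] * 2654435761) %% 1000) < 1000 * cfg$rho) s <- prev
    }
    states[t] <- s
    prev <- s
    row <- teacher$columns[s + 1L, ]
    target[t, ] <- row
    codes[p] <- sample.int(20L, 1L, prob = row)
  }
  list(id = id,
       residues = decode_residues(codes[(burn + 1L):n_ext]),
       profile = profile_matrix(target, source = "teacher"),
       states = states,
       burn_in = if (burn > 0L) decode_residues(codes[seq_len(burn)]) else "")
}

#' Sample a dataset of training pairs
#'
#' Lengths are drawn uniformly from the teacher's `length_range`; pairs are
#' independent given the teacher. Set the R random seed beforehand (or pass
#' `seed`) for reproducibility.
#'
#' @param teacher A `seqprof_teacher`.
#' @param n_pairs Number of pairs (>= 1).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return List of pairs as returned by [sample_pair()].
#' @export
sample_dataset <- function(teacher, n_pairs, seed = NULL) {
  if (n_pairs < 1L) abort("n_pairs must be >= 1")
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  lr <- teacher$config$length_range
  lens <- sample.int(lr[2L] - lr[1L] + 1L, n_pairs, replace = TRUE) + lr[1L] - 1L
  lapply(seq_len(n_pairs), function(i)
    sample_pair(teacher, lens[i], id = sprintf("synthetic_%05d", i)))
}

#' Generate i.i.d. uniform timing sequences
#'
#' Random sequences over the 20-letter alphabet for scalability measurements
#' (step counts / wall time versus length).
#'
#' @param lengths Integer vector of sequence lengths (each >= 1).
#' @param seed Optional integer seed.
#' @return Tibble with columns `id`, `residues`, `length`.
#' @export
make_timing_sequences <- function(lengths, seed = NULL) {
  if (any(lengths < 1L)) abort("lengths must be >= 1")
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  residues <- vapply(lengths, function(n)
    paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = ""), character(1))
  tibble(id = sprintf("timing_%05d", seq_along(lengths)),
         residues = residues, length = as.integer(lengths))
}

#' Context-free baseline column
#'
#' The single fixed profile column used as the context-free reference
#' predictor: the mean of all teacher target rows in a dataset. Any gain of a
#' trained generator over this column measures how much sequence context the
#' generator actually exploits.
#'
#' @param pairs List of pairs from [sample_dataset()].
#' @return Numeric probability vector of length 20.
#' @export
baseline_column <- function(pairs) {
  tot <- Reduce(`+`, lapply(pairs, function(p) colSums(unclass(p$profile))))
  tot / sum(tot)
}
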