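# memoized heavy experiments shared by several acceptance checks

.exp_cache <- new.env(parent = emptyenv())

recovery_run <- function() {
  if (is.null(.exp_cache$recovery)) {
    .exp_cache$recovery <- recovery_experiment(seed = 1)
  }
  .exp_cache$recovery
}

memory_runs <- function() {
  if (is.null(.exp_cache$memory)) {
    .exp_cache$memory <- vapply(1:3, function(s) {
      r <- memory_experiment(seed = s)
      c(full_gain = r$full_gain, truncated_gain = r$truncated_gain)
    }, numeric(2))
  }
  .exp_cache$memory
}
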