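---
title: "De novo profile generation with a word-embedded LSTM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De novo profile generation with a word-embedded LSTM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

A sequence profile (PSSM) assigns every site of a protein a probability
vector over the 20 amino-acid types. `seqprof` generates profiles *de novo*:
a single pass of a recurrent network over the query sequence, no database
search. The network is

1. **Word embedding.** Each residue symbol is looked up in a learned
   `21 × d` table (20 residues plus a padding symbol fixed at zero). Dense
   embeddings use the following layer's parameters more effectively than
   one-hot coding and let the first layer be wide while the recurrent layer
   stays narrower. Reference width `d = 400`; every function accepts
   scaled-down dimensions.
2. **LSTM layer.** A standard forget-gate LSTM with input gate `i`, forget
   gate `f`, candidate `z`, output gate `o`, memory cell
   `c_t = f ∘ c_{t−1} + i ∘ z`, and unit output `v_t = o ∘ tanh(c_t)`
   fed back as the hidden state. The cell is the constant-error pathway
   that carries context across sites; the hidden state is the previous
   unit output. Both are initialized to null vectors at the start of a
   sequence, and the memory-reset (truncated) prediction mode clears both
   — that is the only reading under which "resetting the memory" is well
   defined, since these two vectors are the entire recurrent state.
   Reference unit size `H = 3200` per gate.
3. **Head.** A fully connected `H × 20` layer followed by a softmax, so
   every output row is a probability column. The head reads the LSTM output
   `v_t` only (in the layer diagram the 20-dimensional layer is fed by the
   recurrent layer alone, so no embedding skip-connection is used).

Prediction is causal and linear-time: row `t` depends only on residues
`1..t`, and exactly one LSTM step is executed per site, so generation cost
is O(N) in sequence length — `step_count_scaling()` verifies the exponent
is exactly 1.

## Training scheme

Training imitates teacher profiles: the cost is the root-mean-square error
between the softmax output and the teacher column, averaged over all sites
and residue types of a mini-batch. Optimization is mini-batch Adam.
Regularization is unit dropout (ratio 0.5, inverted scaling) applied to the
embedding output — i.e. between the input layer and the LSTM layer — only
during training passes. Two further elements of the scheme matter:

* **Random start-site cropping.** Each selected pair is cropped from a start
  site drawn uniformly along the sequence (capped at 1000 sites), so the
  network does not overfit N-terminal positions. Targets are cropped with
  the sequence, keeping site correspondence.
* **Epoch subsampling.** An epoch is a fresh uniform subsample (without
  replacement, independent across epochs) of the training pairs, mirroring
  the reference scheme where an epoch is a 40,000-sequence subsample of the
  full corpus. The reference batch size is 200 sequences — we read the
  stated "number of mini-batches ... 200" as the batch *size*, because a
  fixed count of 200 batches is incompatible with a 40,000-sequence epoch.

Unequal lengths inside a batch are handled by sorting the epoch's crops by
length and batching neighbours (lockstep evaluation; sites past a
sequence's end contribute neither to the cost nor to any gradient). The
embedding table keeps a dedicated padding row pinned at zero. Training
stops at a fixed epoch budget while both curves are recorded
(`tidy()`/`autoplot()` on the fit); there is no automatic patience rule.

The whole run is reproducible from the single `seed` field of
`training_config()`: shuffling, the validation split, epoch subsampling,
crop starts and dropout masks all derive from it. Gradients are
backpropagation-through-time derived by hand in the compiled core and are
checked against central finite differences in the test suite (tiny model,
relative error below 1e-5).

## The synthetic teacher

Full-scale training data for this method are profiles computed by iterative
search over millions of sequences — out of reach of a desk-scale package and
external to it. The `synthetic teacher` replaces them with a *known*
context-dependent ground truth:

* Each site has a hidden environment state out of `n_states`. The state is
  a deterministic hash of the `context_k` preceding residues, optionally
  combined with the residue `pair_offset` sites back (the long-range mode —
  a stylized β-strand partner dependency, where the relevant context is
  sequence-distant).
* Each state owns a fixed 20-dim column drawn from `Dirichlet(alpha)`. The
  default `alpha = 0.2` gives peaked, well-separated columns, like conserved
  profile positions; `alpha → ∞` is the uninformative limit.
* The target row at a site is its state's column; the residue emitted at
  the site is *sampled* from that column. Teacher truth (not the empirical
  draw) is the training target, so the Bayes-optimal predictor is exactly
  recoverable and similarity ceilings are known.
* Sites whose *local* context window would extend before position 1 draw on
  hidden "burn-in" residues that are sampled per pair and never revealed.
  Real protein segments likewise carry upstream context that a
  null-initialized recurrent state cannot encode; the hidden prefix
  reproduces that early-position ambiguity in a controlled way. The
  long-range pairing term is simply inactive at sites with no partner
  (`t <= pair_offset`), as for the first strand of a β pair. Causality is
  strict: no target row ever depends on later residues.
* A persistence probability `rho` can lengthen same-state runs; it is
  decided by a deterministic hash of the previous residue so the
  environment stays a pure function of the emitted residues. The default is
  `rho = 0`, keeping the Bayes ceiling exact.

What passing tests on this teacher do **not** show: real profiles have
indels, family structure, position-specific conservation gradients and
composition biases that the teacher does not emulate. The teacher
establishes that the architecture and training scheme can extract
context-dependent column assignments of known range — a necessary, not
sufficient, condition for the real task.

### One residue leaks information

Because the emitted residue is drawn from the target column, the *current*
residue alone carries evidence about its own column. Any evaluation of
context use must therefore compare against predictors that also see the
current site. This is quantifiable by enumerating the Bayes posterior over
states given one residue draw: with `n_states = 8` and `alpha = 1` that
single-residue predictor gains about 0.036 mean cosine over the
context-free column, while the full-context ceiling gain is about 0.23; at
the peaked default (`alpha = 0.2`) the single-residue leak alone is worth
about 0.2. The long-range experiment below is therefore run in the 8-state,
`alpha = 1` regime, where a truncated-context predictor is provably unable
to exceed the baseline by much more than ~0.04, whatever the network
learns.

## Experiments the package runs

* **Parameter recovery** (short context). Teacher with `context_k = 2`,
  defaults otherwise; 2000 training pairs of length 50–100; model
  `d = 16`, `H = 64`; batch size 50, 1000-pair epochs, 60 epochs, dropout
  0.5, Adam step size 2e-3. The trained model's mean positional cosine on
  200 held-out pairs reaches ≈ 0.99 against a context-free baseline of
  ≈ 0.73 (the baseline predictor is the mean teacher row of the training
  set — the natural "single best fixed column").
* **Positional accuracy profile.** The mean-by-position cosine curve shows
  the first `context_k` positions scoring clearly below the plateau — the
  early-position deficit of a null-initialized recurrent generator.
* **Memory power / long-range pairing** (`memory_experiment()`). Teacher
  with `context_k = 0`, `pair_offset = 20`, `n_states = 8`, `alpha = 1`,
  lengths 100–150 (the leak-controlled regime above). One model per seed is
  trained at full context for 180 epochs without dropout (input corruption
  measurably impedes the formation of the 20-step recall), then evaluated
  both normally and with memory reset length `L = 5` — resetting a trained
  predictor's memory, rather than training truncated predictors, matches
  how memory power is probed on the real system. The truncated prediction
  stays at the single-residue leak level (gain ≈ 0.03 over the baseline,
  its window never reaches the pairing partner 20 sites back), while
  full-context prediction exceeds the baseline by several times that
  margin. The long-range recall itself is optimization-bound: the gain
  grows roughly linearly over hundreds of epochs and has not saturated at
  the 180-epoch scale the package runs by default, so the reported
  full-context gain understates the asymptotic memory effect; what the
  experiment establishes is the *contrast* — the full-context generator
  improves by using the remote site while the truncated one provably
  cannot.
* **Ranked-list evaluation.** Superfamily-weighted ROC and pAUC: each
  counted hit contributes `1/|superfamily(query)|`, unknown labels are
  skipped, the FP budget is one FP per query on average (equal to the
  number of superfamilies under this weighting), both axes are normalized
  so pAUC ∈ [0, 1]. Labels follow the standard SCOP convention — same
  superfamily TP, different fold or class FP, same fold but different
  superfamily unknown, self-hits excluded.

## Numerical choices

* Profile rows are validated to sum to 1 within 1e-6 for stored profiles
  and 1e-9 for freshly computed 64-bit softmax outputs.
* The PSSM file format carries a PSI-BLAST-style display block (half-bit
  log-odds `round(2·log2(p/q))`, probabilities clamped at 1e-4 to avoid
  −∞) and a lossless full-precision frequency block, which is the
  authoritative content; round trips reproduce profiles to 1e-9. Background
  frequencies default to uniform 0.05 and are a required, documented input
  — no empirical background is hard-coded.
* HHM match-state scores decode as `p = 2^(−score/1000)` with `*` meaning
  probability zero; rows are renormalized after decoding, so authored
  fixtures are recovered within the 1e-3 quantization of the integer
  encoding.
* The pAUC integrates the step curve trapezoidally and interpolates at the
  FP cutoff (the x-axis only advances on FP hits, so trapezoids reduce to
  rectangles); a hit list exhausted inside the budget extends flat. Ties in
  significance keep stable input order.
* Weight initialization: scaled normals (sd `1/sqrt(fan-in)`), forget-gate
  bias 1 so early training does not flush the memory cell; the padding
  embedding row is pinned at zero and excluded from updates.

## Problem sizes

The package's experiments are sized for a single CPU: 2000 training pairs,
`d = 16`, `H = 64`, 60–180 epochs of 1000 pairs (batch 50). These sizes
were chosen so each experiment completes in minutes while leaving a wide
margin between the measured effects and their thresholds; the reference
configuration (`d = 400`, `H = 3200`, 1.6M sequences, 5000 epochs) is
documented in the defaults of `training_config()` and `init_profiler()` but
is not run anywhere in the package.

## Known limitations

* Single-direction prediction only: the generator reads N- to C-terminal,
  so early sites always carry less context (combining both directions is a
  natural extension, not implemented).
* The teacher's long-range mode couples each site to exactly one earlier
  site at a fixed offset; real β-sheet topologies pair variable, structure-
  dependent offsets.
* No bailout/fallback scoring for sequences the network handles poorly, no
  iterative refinement, and no binary PSI-BLAST checkpoint output (the
  ASCII dialect is this package's interchange format).
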