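---
title: "Hybrid HMM/TDNN modelling of emotional state sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid HMM/TDNN modelling of emotional state sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtmn)
```

## The problem

Speech-based emotion recognition systems usually classify each utterance
from its present acoustic features alone.  But emotional state — stress in
particular — is persistent: the state at time $t$ depends strongly on the
state at $t-1$.  This package models a discrete emotional state over time
with a hybrid of two components:

* a **hidden Markov model (HMM)** over the observed label sequence
  $y_1,\dots,y_T$ (five states in the canonical alphabet: angry,
  high_stress, low_stress, neutral, soft), with initial distribution $\pi$,
  transition matrix $A$ and categorical emission matrix $E$, where
  $E_{ji} = P(y_t = i \mid q_t = j)$ for hidden state $j$; and
* a **time-delay neural network (TDNN)** that predicts the present hidden
  state $q_t$ from the window of prior hidden states
  $q_{t-W},\dots,q_{t-1}$ (binary indicator encoded) together with the
  present feature vector $f_t$ (a speech embedding in the intended
  application; label-conditional Gaussians in the synthetic generator).

The model is deliberately asymmetric: the HMM is fitted to *labels only*
and supplies (a) per-step hidden-state targets by posterior decoding and
(b) the emission matrix that converts hidden-state posteriors into label
posteriors.  The TDNN carries all the feature and temporal-context
information.

## Training

`dtmn()` trains in two stages.

**Stage 1 — Baum–Welch.**  A categorical-emission HMM with `n_hidden`
states (default 80) is initialized by drawing every entry of $\pi$, $A$,
$E$ uniformly on $(0,1)$ and normalizing rows, then fitted to the label
sequences by expectation–maximization with per-step scaling (so sequences
of length 1000+ cannot underflow).  Iteration stops when the total
log-likelihood improves by less than `hmm_tol` (default $10^{-4}$) or at
`hmm_max_iter` (default 100).  Degenerate rows that lose all posterior
mass mid-EM are reset to uniform (floor $10^{-12}$) so no NaN can
propagate.  The trace of log-likelihoods is retained and is non-decreasing
up to $10^{-8}$ numerical slack.  Each sequence's hidden-state targets are
the per-step posterior argmax (ties to the smaller state index) —
posterior decoding, not Viterbi, because per-step targets for a per-step
classifier should maximize per-step marginal probability.

EM converges to a local optimum and categorical HMMs have many.
`hmm_fit_restarts()` runs several random initializations and keeps the one
with the highest final log-likelihood; selection is by likelihood only.
The test suite uses five restarts where it checks recovery of a known
generating model.

**Stage 2 — TDNN by SGD.**  Training tuples are
$(q_{t-W..t-1}, f_t) \to q_t$, with all-zero indicator vectors standing in
for states before the sequence start.  The network is trained with
mini-batch stochastic gradient descent (batch 256, learning rate 0.01,
classical momentum 0.9, 30 epochs by default, shuffled each epoch, fixed
seed giving a bit-identical trajectory) minimizing cross-entropy after the
softmax output.

**Rollout refinement.**  Pure teacher forcing — training only on windows
taken from the decoded paths — leaves the model exposed at prediction
time: recursive decoding feeds the model's own argmax states back into
the window, and one early error creates window patterns never seen during
training, after which errors persist and compound.  This is the classic
exposure-bias failure of recursively decoded models.  `dtmn()` therefore
performs `refine_rounds` (default 2) rounds in which the current network
is rolled out recursively over the training sequences, the windows are
rebuilt from its own fed-back states, and SGD continues; the *targets*
remain the decoded hidden states throughout.  This matches the training
input distribution to the prediction regime, in the spirit of
imitation-learning corrections for exposure bias; the margin it is worth
on persistent data is visible in the preset comparisons the test suite
and acceptance script run.  Setting `refine_rounds = 0` recovers the
pure two-stage procedure.

## The TDNN architecture

Layer contexts are sets of strictly negative absolute offsets into the
prior-state window.  The shipped presets (`tdnn_context()`):

| preset | network | layer 1 | layer 2 | layer 3 |
|--------|---------------|---------------|----------------|---------|
| tdnn1  | {-1}          | {-1}          | {-1}           | {-1, f} |
| tdnn2  | {-2,-1}       | {-2,-1}       | {-1}           | {-1, f} |
| tdnn3  | {-3..-1}      | {-2,-1}       | {-2,-1}        | {-1, f} |
| tdnn4  | {-5..-1}      | {-3..-1}      | {-3,-1}        | {-1, f} |
| tdnn5  | {-7..-1}      | {-3..-1}      | {-5,-3,-1}     | {-1, f} |
| tdnn6  | {-9..-1}      | {-5..-1}      | {-9,-5,-1}     | {-1, f} |
| table2 | {-5..-1}      | {-5..-1}      | {-3,-1}        | {-1, f} |

Forward pass, as implemented:

1. **Layer 1** (time-distributed, weights *untied* across offsets): each
   offset $o$ in the layer-1 context maps its indicator vector through its
   own affine + batch-norm + ReLU, width `hidden_dim`.
2. **Layer 2** (sub-sampled splice): the layer-1 outputs at the layer-2
   offsets are concatenated and passed through affine + batch-norm + ReLU.
   An offset requested by layer 2 but not covered by layer 1 (the `-5` of
   tdnn5, the `-9` of tdnn6) is spliced directly from the raw state
   encoding.
3. **Layer 3** (concatenation): the layer-2 output is concatenated with
   $\beta(f_t)$, a learned affine feature transform initialized near the
   identity.
4. **Layer 4**: fully connected affine + batch-norm + ReLU, width
   `hidden_dim` (default 4000; the desk-scale profile used throughout the
   tests uses 64).
5. **Layer 5**: affine to the `n_hidden` classes and a max-subtracted
   softmax.

Design notes on genuinely open points:

* The published layer contexts do not state whether sub-sampling ties
  weights across offsets as in classic TDNNs; weights are untied here,
  which is the more flexible reading and costs little at these widths.
* Batch normalization is placed after each affine and before each ReLU in
  layers 1, 2 and 4; inference uses frozen running moments (momentum 0.9),
  so `tdnn_forward(..., mode = "infer")` is a pure function of parameters
  and inputs.
* The single-offset variant tdnn1 runs through the same layered code path
  restricted to offset −1; its information content equals the one-layer
  softmax formulation it descends from.
* Pre-sequence boundaries use the all-zero encoding rather than a phantom
  start state, so the very first step is predicted from features alone.

## Prediction

`predict()` runs the recursion $t = 1,\dots,T$: the TDNN (inference mode)
maps the fed-back window and $f_t$ to the hidden posterior
$P(q_t = j \mid f)$; the hard argmax $\hat q_t$ (ties to the smaller
index) enters the window for later steps, while the *soft* posterior is
mapped through the emission matrix,

$$P(y_t = i \mid f) = \sum_j E_{ji}\, P(q_t = j \mid f),$$

whose rows are asserted to sum to 1 on every prediction.  The label is
the row argmax, ties again to the smaller index.  The initial distribution
$\pi$ is not used at prediction time: the first window is all-absent.
Feeding back the hard argmax while propagating the soft posterior keeps
the recursion consistent with the single-value feedback the method
defines, without discarding posterior mass in the label mapping.

## The synthetic generator

`synth_generate()` emulates the structure of labeled stress-speech
embeddings: per group ("M", "F"), labels follow a ground-truth 5-state
Markov chain; features are unit-variance Gaussians centred on a per-label
mean at distance `separation` along distinct axes; observed labels can be
flipped uniformly at a `noise_rate` while features always follow the true
label, so feature overlap and label noise are independent knobs.  The two
default group chains share their diagonal but push their off-diagonal
mass toward opposite states (angry vs soft), mimicking a qualitative
male/female contrast without copying any corpus-derived numbers.

Presets fix the study conditions used by the tests and the acceptance
script:

* `separable` — separation 4.0, diagonal 0.6: features alone decide.
* `overlapping` — separation 1.5, diagonal 0.6.
* `persistent` — separation 1.5, every chain diagonal exactly 0.9:
  temporal context is genuinely informative.
* `iid` — every transition probability 0.2: no temporal signal.

What the generator does *not* emulate: embedding geometry beyond
class-conditional Gaussians (real speech embeddings have anisotropic,
speaker-dependent structure), utterances of grossly different lengths,
and any dependence of features on the *previous* state.  Passing tests on
these presets therefore demonstrates correctness of the machinery and the
claimed qualitative orderings, not performance on real stress-speech
corpora.

## Evaluation and study conditions

The prediction error rate (PER) is the percentage of time steps whose
predicted label differs from the truth, pooled over sequences
(micro-average); `evaluate_model()` also returns the confusion matrix,
from which the pooled PER is exactly recomputable.  The comparator,
`memoryless_fit()`, is a single softmax layer on $f_t$ trained by the
same SGD machinery — it isolates exactly what temporal context adds.

The desk-scale profile used by the test suite and `scripts/acceptance.R`:
50 sequences of 200 steps per preset (25 per group), feature dimension 8,
10 hidden states, hidden width 64, 30 epochs per pass (one teacher-forced
pass plus two refinement rounds), Baum–Welch capped at 100 iterations,
five independent seeds, and a 20% per-sequence holdout for every reported
PER.  These sizes
were chosen so that each quantity is estimated from 10,000 generated steps
while a full run stays comfortably within a single-CPU desk session.
The hidden-state and context ablations (`ablate_hidden_states()`,
`ablate_contexts()`) default to five repeats with seeds `seed..seed+4`;
the context sweep refits only the TDNN per variant, sharing the HMM stage
within a repeat, so the context factor is isolated.

## Numerical choices

* Scaled (per-step normalized) forward–backward, implemented in C++, with
  the log-likelihood accumulated from the scaling constants; the test
  suite checks it against brute-force path enumeration at $10^{-10}$.
* Softmax always subtracts the row maximum before exponentiating.
* Batch-norm epsilon is $10^{-5}$; running moments are frozen for
  inference.
* All argmax tie-breaks go to the smallest index, everywhere.
* Stationary distributions solve the left fixed-point system directly and
  *refuse* reducible or periodic chains (graph reachability plus the
  cycle-gcd period test) instead of silently returning an eigenvector.
* Chain rows never observed as a source default to uniform
  (`zero_row_rule = "uniform"`); no smoothing is applied by default since
  exact zero counts should stay exact zeros.

## Known limitations

* **Hidden states are nuisance variables.**  With 10–80 hidden states
  over 5 labels the HMM is over-complete; recovered states are not
  interpretable and are never reported as such.
* **Temporally unstructured data is the hard case for the architecture.**
  On iid labels, EM has no temporal signal to anchor the hidden states:
  random-init Baum–Welch settles in blurry-emission optima whose decoded
  states determine the label imperfectly, and running EM longer makes
  this worse — the likelihood keeps rising by encoding spurious context
  patterns into the states, and likelihood-selected restarts cannot help
  because the sharp and blurry optima are nearly equivalent in
  likelihood.  The label → hidden → label round trip then costs PER
  points even for a perfectly calibrated network, so the DTMN trails a
  plain feature classifier on iid data.  The acceptance script reports
  both iid medians so this gap is measured, not hidden.  On persistent
  data — the regime the method was designed for, and the regime real
  emotional speech occupies — the same EM sharpens to near-deterministic
  emissions and the DTMN clearly beats the memoryless baseline (again
  both medians are reported).
* **Exposure bias is mitigated, not eliminated.**  Rollout refinement
  recovers much of the teacher-forced accuracy; residual drift remains on
  long sequences.
* Wall-clock benchmarking and external baseline families (KNN, Bayesian
  networks, LSTMs, recursive Markov networks) are out of scope.
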