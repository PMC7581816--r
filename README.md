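# dtmn — deep time-delay Markov networks for emotional state sequences

Speech-based stress and emotion recognition usually classifies each moment
from its present acoustic features alone, yet emotional state is strongly
persistent: knowing the recent past sharpens the present prediction.
`dtmn` implements a hybrid sequence model for discrete emotional states
(canonically angry, high_stress, low_stress, neutral, soft) over
time-series of speech-embedding features:

* a **categorical-emission hidden Markov model** fitted to label sequences
  by Baum–Welch (scaled forward–backward in C++), supplying per-step
  hidden-state targets by posterior decoding and the emission matrix
  `E[j, i] = P(y = i | q = j)`;
* a **time-delay neural network (TDNN)**, written from scratch (mini-batch
  SGD with momentum, batch normalization, sub-sampled temporal splicing),
  that predicts the present hidden state from the binary-encoded window of
  prior hidden states plus the present feature vector;
* recursive **prediction**: the network's argmax state is fed back into
  the window while its soft posterior is mapped to the label posterior
  `P(y_t = i | f) = Σ_j E[j, i] · P(q_t = j | f)`;
* a **finite Markov chain** estimator for the 5×5 emotional transition
  structure per group (e.g. male/female), with stationary-distribution
  queries;
* a **synthetic generator** (ground-truth Markov chains × label-conditional
  Gaussian features) standing in for license-restricted stress-speech
  corpora, so every stage is testable end to end;
* an **evaluation kit**: prediction error rate (PER), confusion matrices,
  a memoryless softmax baseline trained by the same SGD machinery, and the
  hidden-state-count and temporal-context ablations.

It is an R package in the classic modelling idiom: `dtmn()` fits, the
returned object has `print`, `summary` and `predict` methods, and
everything is reproducible from explicit seeds.

## Worked example

```r
library(dtmn)

g  <- synth_generate(synth_preset("persistent", n_sequences = 10,
                                  length = 120, D = 8, seed = 42))
sp <- split_holdout(g$data, 0.2, seed = 42)

model <- dtmn(sp$train, n_hidden = 10, hidden_dim = 64,
              control = tdnn_control(epochs = 20, seed = 42),
              hmm_max_iter = 100, seed = 42)
model
#> Deep time-delay Markov network
#>   Alphabet:   angry, high_stress, low_stress, neutral, soft
#>   HMM:        N = 10 hidden states, 100 Baum-Welch iterations (loglik -934.682)
#>   TDNN:       context 'tdnn4', hidden width 64, final loss 0.9265
#>   Features:   D = 8

evaluate_model(model, sp$test)
#> Prediction error rate: 25.83% over 480 steps (4 sequences)
#> Confusion matrix (rows = true):
#>              pred
#> true          angry high_stress low_stress neutral soft
#>   angry         126           3         10       5   19
#>   high_stress     1          63          2       1   10
#>   low_stress      9           3         38      17    4
#>   neutral        11           2          0      51    0
#>   soft            5           8         10       4   78

bl <- memoryless_fit(sp$train, tdnn_control(epochs = 20, seed = 42))
evaluate_memoryless(bl, sp$test)
#> [1] 38.54167
```

The "persistent" preset draws labels from chains with 0.9 diagonals and
deliberately overlapping features (class separation 1.5), so features
alone are ambiguous: the memoryless baseline errs on 38.5% of steps while
the DTMN, exploiting the fed-back temporal context, errs on 25.8%.
Transition structure is then modelled from the predicted labels:

```r
preds <- predict(model, sp$test)
pred_set <- sp$test
for (i in seq_along(preds)) pred_set$sequences[[i]]$y <- preds[[i]]$labels
chain_by_group(pred_set)$M
#> Emotional state transition chain [group: M] -- 357 observed transitions
#> Transition probabilities P(i -> j), rows = source state:
#>              to
#> from          angry high_stress low_stress neutral soft
#>   angry        0.78        0.05       0.05    0.04 0.08
#>   high_stress  0.00        0.78       0.05    0.04 0.13
#>   low_stress   0.17        0.06       0.61    0.03 0.14
#>   neutral      0.08        0.06       0.02    0.79 0.06
#>   soft         0.12        0.07       0.04    0.03 0.73
```

Diagonal dominance — emotions rarely change between adjacent steps — is
recovered from predictions alone.  `stationary_distribution()` summarizes
a chain's long-run occupancy (it refuses reducible or periodic chains).

Sequence tables are plain TSV (`read_sequence_table()` /
`write_sequence_table()`, bit-faithful round trip); models and chains
serialize to JSON (`write_dtmn()`, `write_chains()`).  A thin CLI over
these functions lives in `inst/cli/dtmn.R`
(`simulate | train | predict | evaluate | chain | ablate`).

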