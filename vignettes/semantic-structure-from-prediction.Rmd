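---
title: "How prediction-based networks acquire semantic structure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How prediction-based networks acquire semantic structure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the approach

`cdslm` studies a specific claim from distributional-learning theory: that a
learner which does nothing but predict the next word in naturalistic,
child-directed speech will, as a side effect, acquire abstract and
hierarchically organized semantic knowledge. The package implements three
learners from scratch — a simple recurrent network (SRN), an LSTM, and
skip-gram with negative sampling — together with the corpus machinery, the
training regime, and the full evaluation stack needed to interrogate what
the learners know. Because the interesting empirical work happens on large
transcript corpora that cannot ship with a package, `cdslm` also includes a
synthetic child-directed-speech generator with *planted* semantic
categories, so every stage of the pipeline can be exercised and validated
end to end on data whose ground truth is known exactly.

## Corpus preparation

Input is plain text, one utterance per line, with a per-document child-age
sidecar. `normalize_utterance()` lower-cases, splits on whitespace, and
keeps sentence-boundary punctuation (`.`, `!`, `,`, `?`) as standalone
tokens — a crude stand-in for the prosodic cues that accompany utterance
boundaries. Spelling variants collapse through an alias table and proper
names become gender tokens (`FNAME`/`MNAME`). `morph_split()` separates
plural, possessive, diminutive, past-tense and progressive endings into
tokens of their own; it is deliberately a rule-based splitter gated by a
caller-supplied stem lexicon, because any full morphological parser would
be both heavier and no better defined. Tokens such as `bus` are protected
simply because `bu` is not a known stem.

`build_vocabulary()` ranks types by frequency and keeps the top
`size_limit - 1`, with the reserved `UNKNOWN` symbol occupying the final
slot so the model's input/output width equals `size_limit` exactly (4096 by
default). Ties at the cutoff are broken lexicographically so builds are
reproducible; whether punctuation competes for inventory slots is a
substantive choice — here it does, since punctuation tokens are tokens like
any other. The train/test split is at the document level, seeded, and both
halves remain age-ordered; age ties are broken by document id so ordering
is total.

`partition_corpus()` cuts the encoded, age-ordered training stream into
`n_partitions` equal blocks of `floor(N / n_partitions)` tokens, dropping
and reporting any remainder. The reference corpus arithmetic — 5,244,672
tokens into 256 partitions of exactly 20,487 — leaves no remainder, so the
drop policy only matters for other corpus sizes; dropping (rather than
padding or a ragged final block) keeps every partition statistically
interchangeable.

## The learners

All three models share a localist input encoding: one of `V` units active
per word, which by construction carries no similarity information — every
regularity the models exhibit must be learned from the word sequence.

**SRN.** The hidden state is `tanh(W_in[x,] + t(W_rec) h_prev)` with 512
units in the reference configuration; the output layer is a softmax over
the full inventory (computed with max-subtraction so arbitrary logits are
safe).

**LSTM.** The classic gate set, no peepholes: input, forget and output
gates are sigmoids of affine functions of the current input and previous
gated output; the memory cell accumulates `f * c_prev + i * tanh(g)`
without squashing; the output is `o * tanh(c)`. Gate biases start at zero
(a forget-bias offset is available but defaults to 0, since the classic
description has none).

**Skip-gram.** Input and output embedding tables; the training objective
is negative sampling — `log sigma(u_ctx . v_c)` for the observed pair plus
`log sigma(-u . v_c)` for `k = 5` noise words drawn from the smoothed
(power-0.75) unigram distribution, with collisions with the true context
word redrawn. Negative sampling is used instead of hierarchical softmax
deliberately: the two are interchangeable in performance for this task and
negative sampling has the simpler, better-understood gradient. No
frequent-word subsampling is applied by default: it requires corpus-global
frequency knowledge that an online learner would not have. Output
embeddings initialize at zero (the reference convention), so an untrained
word's representation is exactly its random input row.

**Initialization.** Weights draw from a truncated normal, mean zero,
nominal sd `1/m` with `m` the size of the layer the weights project into,
truncated at ±2 sd. Note the truncation shrinks the *realized* sd to about
0.88 of nominal — the package's tests assert the truncated-normal closed
form, not the nominal value. The output bias starts at exactly zero.

**Windows.** A training example is the current word plus up to six
predecessors, with the following word as the prediction target; the
recurrence starts from a reset (zero) state at the window's first token.
Corpus-initial windows are simply shorter — implemented by masking columns
in the batched forward/backward rather than padding with a reserved symbol,
which is mathematically identical to starting the short window at the
reset state and spends no inventory slot. By default only the final step's
prediction incurs loss (one prediction error per word); scoring every step
of the window is available behind `all_steps = TRUE`, because the
alternative reading is defensible — the package treats last-step-only as
canonical since each word then contributes exactly one error.

**Gradient correctness.** Truncated backpropagation through time for both
recurrent models, and the negative-sampling gradient, are verified against
central finite differences on toy networks (relative error below 1e-4);
this is the package's central correctness oracle and is run in the test
suite, not assumed.

## The age-ordered local-iteration training regime

Instead of epochs over the whole corpus, each age-ordered partition is
presented `local_iterations` times consecutively before moving on:
`1,1,1,1,2,2,2,2,3,3,3,3` for three partitions and four repetitions. This
models day-scale consolidation of linguistic experience and lets the model
see input in an age-appropriate order. `local_iterations` has no canonical
value and is therefore a required configuration field; the worked example's
4 is used in the unit tests, and the package's own synthetic study uses 2
(see below).

Optimization is Adagrad (`eps = 1e-8`; the accumulators are never reset,
including across partition boundaries) at learning rate 0.01 with
mini-batches of 64 windows. The mini-batch gradient is the *mean* over the
windows, so the update reflects the average prediction error; mean rather
than sum keeps the effective step size comparable across batch sizes, and
a batch-size-1 run recovers the same qualitative category structure (this
is a test). Recurrent training involves no sampling, so a fit is
bit-reproducible from its initialization seed on one thread.

## Representations and similarity

For the recurrent models a word's representation is *contextual*: the
corpus is re-input without weight updates, the hidden state at the end of
every window is recorded, and all states whose final token is the word are
averaged (`extract_contextual_reps()`). The un-averaged per-occurrence
states (`occurrence_states()`) expose polysemy: a word used in two
unrelated frames shows distinct state clusters and a lower mean pairwise
correlation than an unambiguous word. For skip-gram the representation is
the input-embedding row.

Similarity is the Pearson correlation of representation vectors (Spearman
behind a flag). Two matrix forms are used: probe-by-vocabulary for
inter-model reliability, and square probe-by-probe for classification.
Reliability correlates two models' flattened matrices, excluding self-pairs
(row word = column word), whose uninformative 1s would inflate agreement.
Words that never occur in the evaluation pass have undefined rows and are
dropped with a warning rather than imputed.

## Evaluation

**Perplexity** is `exp` of the mean negative log probability of each next
word, with windows built exactly as in training: 1 for perfect prediction,
`k` for a model that treats `k` words as equally likely, about the
inventory size for an untrained model.

**Balanced accuracy.** Every probe pair is judged same/different category
by thresholding similarity against `r` on a 0–1 grid of step 0.001. Per
probe: sensitivity over its same-category partners, specificity over its
different-category partners, balanced accuracy their mean — removing the
bias from the overwhelming majority of pairs being different-category. The
summary is the across-probe mean at the single threshold maximizing it
(a global threshold, not per-probe optima). Tie similarities `S = r` count
as "different", consistent with a hit requiring `S > r`; negative
correlations fall below every grid threshold by design. Probes with no
same-category partner (and, degenerately, probe sets with a single
category) are excluded with a warning. The vectorized sweep is tested for
exact agreement with an exhaustive enumeration oracle on random small probe
sets.

**Structure.** `category_similarity_matrix()` removes the self-similarity
diagonal, averages within- and between-category pairs, and reorders rows by
average-linkage hierarchical clustering on `1 - S` (the linkage is a
package choice; nothing canonical exists). The same clustering applied
within one category exposes latent hierarchy among its members.
`pca_loadings()` runs centered, unscaled PCA over word representations —
unscaled because hidden units share one activation range — returning
per-word scores and variance fractions. t-SNE is deliberately not wrapped:
it is non-deterministic and purely a visualization aid.

## The synthetic generator and what it does (not) show

`generator_config()` defaults encode the package's study conditions: 10
categories × 8 target words, 6 context frames per category with zero
overlap, Zipf exponent 1 over target words (rank assignment shuffled so
frequency is not confounded with category), 20 age-ordered documents of
about 10,000 tokens (~200k total), no polysemy, no age drift. Frames are
finite utterance templates — enough to create substitutability structure
and cheap to brute-force — rather than a grammar; synthetic ages are
document indices; drift linearly interpolates between two frame mixtures.
Category structure is planted *purely distributionally*: a bag-of-contexts
nearest-centroid classifier recovers it at 100% from co-occurrence counts
alone, which is the oracle any successful learner is implicitly compared
against.

The generator's corpus is far easier than real child-directed speech: no
syntax, no referential ambiguity beyond what is injected, disjoint
contexts. Passing the package's synthetic studies therefore shows that the
learners and the evaluation stack behave as designed — it does not show
that any particular accuracy level would transfer to real transcripts,
where the reference numbers (test perplexity in the low 40s, balanced
accuracies near 70%) come from hours of training on millions of words.

The package's own synthetic study — the one its acceptance tests run —
trains two SRNs, two LSTMs and one skip-gram with hidden size 64,
8 partitions, `local_iterations = 2`, and 5 skip-gram epochs. These sizes
were chosen once as a desk-scale configuration: the easy corpus saturates
well before the reference settings (512 hidden units, 256 partitions, 20
epochs) would, and all three architectures reach balanced accuracy near
1.0, within-architecture replicate reliability above cross-architecture
reliability, and a diagonally dominant category matrix.

## Numerical and degenerate-input choices

* Softmax uses max-subtraction; probabilities sum to 1 within 1e-12.
* Vocabulary frequency ties: lexicographic. Nearest-neighbor similarity
  ties: lexicographic. Best-threshold ties: the lowest such threshold
  (`which.max`).
* Zero-variance representation vectors yield `NA` similarities with a
  warning; words with no occurrences yield undefined rows.
* `UNKNOWN` occupies an inventory slot even when unused, so model width
  always equals the configured inventory size.
* Empty utterance lines tokenize to empty sequences and are dropped when
  reading a corpus directory.
* The skip-gram chunked trainer aggregates per-row gradients within a
  chunk before applying them; at learning rates this size the difference
  from strictly sequential updates is far below run-to-run seed variance.

## Known limitations

* Pure R with BLAS-level batching: ample for the desk-scale studies here,
  but reproducing corpus-scale reference numbers (millions of tokens, 512
  hidden units, 10 replicates) would take hours and an external corpus.
* The morphological splitter is a heuristic; it is pluggable precisely so
  a real parser can replace it.
* CHAT-format transcripts must be flattened to plain utterance lines
  before ingestion; the package does not parse CHAT markup.
* Checkpoints live in memory as R objects; no HDF5 container is used.
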