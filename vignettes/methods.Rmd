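---
title: "Attention-based read-level phenotype classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-based read-level phenotype classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampatt)
```

## The problem

Conventional microbiome classification first collapses amplicon reads into
an OTU/ASV abundance table and then classifies the table. That pipeline
discards the sequence content of individual reads and requires manual
interpretation to find out *which* nucleotides carried the signal. `ampatt`
takes the opposite route: it trains a neural classifier that maps a single
16S rRNA read to the phenotype of the sample it came from (body site,
disease status, or a taxon label), and only then aggregates read-level
outputs into sample-level predictions. Because the classifier carries an
explicit attention mechanism, each prediction comes with a per-position
importance vector, which can be turned into biological statements about
informative nucleotide regions — for 16S, typically hypervariable regions.

## The read classifier

A read of length $T$ is one-hot encoded into a $T \times 4$ matrix on the
fixed channel order A, C, G, T. IUPAC ambiguity codes are encoded as the
uniform distribution over their compatible bases (N = 0.25 on each
channel); positions past the end of a shorter read are zero vectors, so
each row sums to 1 for a real base and 0 for padding.

The network is:

1. **Convolutional blocks.** `n_conv_blocks` (default 2) blocks of
   same-padded 1-D convolution with window $W = 9$ and $N_c$ output
   channels, each followed by batch normalization and ReLU. The output is a
   $T \times N_c$ matrix of local $k$-mer features. Two blocks give the
   attention layer a receptive field of 17 bases while keeping the model
   small; the block count is a configuration knob.
2. **Bidirectional LSTM.** $N_h/2$ units per direction, concatenated to an
   $N_h$-dimensional hidden state $h_t$ per position, giving a
   $T \times N_h$ matrix that encodes longer-range sequence context.
3. **Soft attention.** Each position is scored
   $s_t = w_2^{\top}\tanh(W_1 h_t + b_1)$ with $W_1 \in
   \mathbb{R}^{N_a \times N_h}$, and the scores are softmax-normalized over
   positions into the attention vector $\alpha$ ($\alpha_t \ge 0$,
   $\sum_t \alpha_t = 1$). The attention is computed from the LSTM hidden
   states alone, the standard form of soft attention for sequence
   classification.
4. **Read embedding and output.** The read embedding is the
   attention-weighted sum $r = \sum_t \alpha_t h_t$; a dense layer with
   softmax over the $N_y$ classes produces the class scores.

Training minimizes cross-entropy (binary when $N_y = 2$, categorical
otherwise — for a two-class softmax the two coincide; the name is recorded
in the training log) with Adam at learning rate 0.001 and default moment
parameters, for 10 epochs by default. Reads are labelled by their sample's
phenotype, pooled and reshuffled each epoch under the configured seed.

No deep-learning framework is involved: the forward pass, backpropagation
(including through batch normalization and both LSTM directions) and Adam
are implemented directly in vectorized R on BLAS-backed matrix products.
The test suite validates every analytic gradient against central finite
differences to a relative tolerance of $10^{-4}$, which is the meaningful
correctness oracle for hand-written backpropagation.

### Numerical choices

* Softmax is computed with the max-subtraction trick; cross-entropy clamps
  probabilities at $10^{-12}$.
* Batch normalization uses $\epsilon = 10^{-5}$ and momentum 0.9 for its
  running inference statistics; normalization is per channel over all reads
  and positions in the minibatch.
* Weights are Glorot-uniform; LSTM forget-gate biases start at 1 so memory
  cells are initially open.
* One integer seed drives initialization and shuffling. Same-platform
  reruns are bit-reproducible; bit-identity across BLAS builds is not
  promised.
* Batch size defaults to 512; the packaged experiments use 128, which at
  desk scale gives more optimizer updates per epoch at negligible cost.
* Variable-length sequence sets are right-padded to the nearest multiple of
  100 bases and trained bucket by bucket; all network weights are shared
  across positions, so one model serves every bucket length.

## Sample-level prediction

Three aggregation strategies, plus one sequence-only baseline:

* **Majority vote.** Each read votes for every class whose score strictly
  exceeds chance $1/N$; a read with exactly no class above chance casts a
  single vote for its argmax class. The sample label is the argmax of the
  tally, ties broken alphabetically. The fallback and tie-break rules are
  this package's explicit choices (any deterministic rule works; these are
  documented so results are reproducible).
* **Averaged embedding.** The arithmetic mean of a sample's read embeddings
  is the sample feature vector; a Random Forest (100 trees) learns the
  phenotype.
* **Pseudo OTU.** Training-read embeddings are clustered with Euclidean
  k-means into $k$ clusters (default 1000; k-means++ seeding, 10 restarts,
  best within-cluster sum of squares kept). Each sample's reads are
  assigned to their nearest centroid (ties to the lowest index), the counts
  are row-normalized into relative abundances, and a Random Forest is
  trained on the table. Empty clusters stay as zero-use columns so the
  table always has $k$ columns.
* **k-mer baseline.** Row-normalized counts of all overlapping 9-mers per
  sample; 9 matches the convolution window, making this the hand-crafted
  counterpart of the first conv layer's features.

## Interpretation

For a group of equal-length reads the per-position Shannon entropy in bits
is

$$H(l) = -\sum_b f(b,l)\,\log_2 f(b,l),$$

where $f(b,l)$ is the observed frequency of base $b$ at position $l$
(gaps/ambiguity characters are excluded from the counts at their position,
and $0\log 0 = 0$). Class-conditional logo letter heights are

$$S_c(b,l) = f_c(b,l)\, H(l),$$

so heights stack to the pooled entropy in every class and vanish at
conserved columns. The model-side importance measure is the class-wise mean
attention

$$A(c,l) = \overline{\alpha}_c(l),$$

grouped either by predicted label (phenotype models, where a read's true
habitat is genuinely ambiguous) or by true label (taxonomic models).
Attention profiles are optionally smoothed by a centered moving average of
window 9 — the convolution window — truncating at the read ends, which
keeps the output length $T$ and preserves interior mass.

When insertions/deletions shift homologous positions across sequences, the
attention vectors can be mapped onto an externally computed multiple
sequence alignment: the attention value of ungapped position $j$ lands in
the alignment column holding residue $j$, gap columns are undefined (not
zero) for that sequence, and column means average defined entries only.
This deliberately does **not** renormalize rows after alignment, so a
sequence's mapped attention still sums to 1 over its defined columns and
deleting its gap columns recovers the input vector bit-exactly. Per-region
attention budgets sum mean attention inside 1-based inclusive breakpoints
(e.g. published V1–V9 tables); a partition of $[1, T]$ closes the budget at
1.

Read embeddings are ordinated by covariance PCA (centered, unscaled — the
embedding axes share one scale) onto the top two components; component
signs are fixed by making each component's largest-magnitude loading
positive so projections are deterministic.

## The synthetic generator

Real amplicon data confound phenotype signal with taxonomic composition,
sequencing noise and alignment shifts. The generator isolates the
ingredient the classifier is supposed to find: per genus a random backbone
of length $T$ shared by all classes, with class-discriminative bases
planted only inside known windows, plus i.i.d. per-base substitutions
(uniform over the three alternatives) and optional single-base indels with
re-trimming/padding back to $T$. Genus composition is uniform across
classes by default, so the *only* class signal is the planted window —
making "did attention find the window?" a question with a known answer.

Default conditions are desk-scale: 3 classes × 10 samples × 500 reads of
100 bases, one 10-base window at positions 46–55, substitution rate 0.01,
no indels. These defaults are what the packaged end-to-end experiments use:
a model with $N_c = 64$, $N_h = 32$, $N_a = 16$, two conv blocks, batch
size 128, trained 5 epochs (the training set is one default draw,
15,000 reads; the test set an independent draw of 10 samples per class),
and $k = 100$ Pseudo OTU clusters, sized to the 15,000 training embeddings.
On one CPU the full simulate → train → predict → interpret loop runs in
about 10 minutes.

What the generator does **not** emulate: real 16S phylogenetic covariance
structure, chimeras, PCR/sequencer error profiles, length variation beyond
single indels, and compositional effects between taxa. Passing the packaged
end-to-end checks therefore demonstrates that the machinery recovers a
planted, localized, class-pure signal at realistic noise — not that any
particular real dataset will reach a given accuracy.

## Design decisions in ambiguous corners

* **Ambiguity codes** are encoded fractionally (uniform over compatible
  bases) rather than dropped, so no read positions are lost.
* **Read trimming** keeps `length` bases after dropping `offset` leading
  bases; short remainders pass through and are zero-padded at encoding.
* **Attention from hidden states only** (not conv features): the standard
  soft-attention form; the conv features influence attention only through
  the LSTM.
* **Vote threshold is strictly greater than** $1/N$: "greater than chance".
* **Zero-read samples** are excluded from Random Forest training with a
  warning, and their relative-abundance rows are NA rather than silently 0.
* **Label-shuffled control.** The end-to-end suite includes a control in
  which *read* labels are permuted before training. Two subtleties are
  worth recording. First, permuting labels at the *sample* level is too
  weak a control at desk scale: with 10 samples per class a permutation
  often leaves each true class's plurality label unchanged, and a model
  that learns the empirical per-archetype label imbalance then scores far
  above chance even though the labels are "shuffled". Second, even under a
  read-level permutation a trained model's predictions are constant within
  each of the $G = n_\mathrm{genera} \times n_\mathrm{classes}$ read
  archetypes (it learns each archetype's tiny empirical label imbalance),
  so its accuracy behaves like (archetypes won)$/G$: the correct null
  standard error for the chance-level check is the archetype-level
  $\sqrt{p(1-p)/G}$, not the binomial standard error over the read count,
  which would understate the null spread by two orders of magnitude.

## Known limitations

* Training is CPU-bound R; desk-scale problems (tens of thousands of
  reads, $T \le 250$) train in minutes, but the implementation is not
  intended for million-read GPU-scale corpora.
* Bucketed variable-length training shares batch-norm statistics across
  buckets; extremely skewed bucket sizes may bias the running statistics.
* The alignment mapper consumes an externally produced MSA; it does not
  align.
* Attention localization is an approximation of nucleotide importance: the
  weights score LSTM states whose receptive fields span neighboring bases,
  so single-base attribution is inherently smoothed.
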