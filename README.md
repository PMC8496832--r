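# ampatt — attention-based read-level phenotype classification for 16S rRNA amplicons

`ampatt` classifies **individual amplicon reads** to the phenotype of the
sample they came from — body site, disease status, or a taxon label — with
a hybrid convolutional / bidirectional-LSTM / soft-attention neural
network, then aggregates the read-level outputs into **sample-level**
predictions. It is aimed at microbiome researchers who want phenotype
prediction *and* an automatic answer to "which nucleotides carried the
signal?", without building OTU/ASV tables first.

## The model

A read of length *T* is one-hot encoded (*T* × 4, channel order A,C,G,T;
IUPAC ambiguity codes become fractional rows, padding rows are zero) and
passed through:

1. same-padded 1-D convolutional blocks (window *W* = 9, *N<sub>c</sub>*
   channels, batch-norm + ReLU) → *T* × *N<sub>c</sub>* local k-mer
   features;
2. a bidirectional LSTM (*N<sub>h</sub>*/2 units per direction) →
   *T* × *N<sub>h</sub>* hidden states *h<sub>t</sub>*;
3. soft attention: *s<sub>t</sub> = w₂ᵀ tanh(W₁h<sub>t</sub> + b₁)*,
   softmax over positions → attention weights *α* (non-negative, sum 1);
4. the read embedding *r = Σ<sub>t</sub> α<sub>t</sub>h<sub>t</sub>* and a
   dense softmax over the *N<sub>y</sub>* classes.

Training is minibatch Adam (lr 0.001) on cross-entropy over reads labelled
by their sample's phenotype. The forward pass, backpropagation and Adam are
implemented directly in vectorized R (the test suite checks every analytic
gradient against finite differences).

Sample-level predictions come from three aggregators: **majority vote**
(each read votes for every class scoring strictly above chance 1/N),
**averaged sample embedding** + Random Forest, and **Pseudo OTU** tables
(k-means clustering of read embeddings; per-sample cluster relative
abundances) + Random Forest, plus a 9-mer frequency-table baseline.

Interpretation tools implement per-position Shannon entropy
*H(l) = −Σ<sub>b</sub> f(b,l) log₂ f(b,l)*, entropy-scaled class logos
*S<sub>c</sub>(b,l) = f<sub>c</sub>(b,l)·H(l)*, class-wise mean attention
*A(c,l)* with window-9 moving-average smoothing, attention mapped onto an
external multiple sequence alignment, per-variable-region (V1–V9)
attention budgets, and 2-D PCA ordination of embeddings.

A synthetic-data module generates multi-sample datasets with genus-like
reference clusters and class-discriminative bases planted at known loci,
so every claim above is testable against exact ground truth.

## Worked example

```r
library(ampatt)

# a 3-class dataset: 10 samples/class x 500 reads of 100 bases; the classes
# differ only in a 10-base window at positions 46-55 (1% substitution noise)
spec  <- synthetic_spec(seed = 11)
train <- generate_samples(spec, split = "train", seed = 11)
test  <- generate_samples(spec, split = "test",  seed = 12)

hp <- hyperparams(T = 100, N_y = 3, N_c = 64, N_h = 32,
                  epochs = 5, batch_size = 128, seed = 11)
model <- train_model(build_model(hp),
                     encode_reads(train$reads$sequence, 100),
                     train$ground_truth$class, verbose = TRUE)
#> epoch 1/5: loss 0.1893, accuracy 0.9647
#> epoch 2/5: loss 0.0025, accuracy 1.0000
#> ...
#> epoch 5/5: loss 0.0005, accuracy 1.0000

pred <- predict_reads(model, encode_reads(test$reads$sequence, 100))
mean(model$class_names[max.col(pred$scores)] == test$ground_truth$class)
#> [1] 0.9998667

# does the attention find the planted window (positions 46-55)?
mean(rowSums(pred$attention[, 46:55]))
#> [1] 0.8327719    # vs 0.10 expected under uniform attention
```

The model recovers the planted signal: read-level test accuracy is ~1.0
and 83% of the attention mass concentrates on the 10% of positions that
actually distinguish the classes.

A single read's scores feed the vote caller:

```r
majority_vote(rbind(c(0.51, 0.43, 0.06)), c("gut", "skin", "oral"))
#> vote tally (threshold 0.3333): gut=1, skin=1, oral=0 -> gut
```

Both `gut` (0.51) and `skin` (0.43) exceed chance 1/3, so each gains one
vote; `oral` gains none.

The same pipeline is scriptable from a shell via the installed CLI
(`inst/cli/ampatt.R`): `simulate`, `train`, `predict`, `interpret`
subcommands with a flat key=value config.

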