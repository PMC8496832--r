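Package: ampatt
Title: Attention-Based Read-Level Phenotype Classification for 16S rRNA
    Amplicon Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains a hybrid convolutional / bidirectional-LSTM / soft-attention
    neural network that classifies individual 16S rRNA amplicon reads by the
    phenotype of the sample they came from, then aggregates read-level outputs
    into sample-level predictions by majority vote, averaged read embeddings,
    or k-means "Pseudo OTU" tables fed to a Random Forest. Attention weights
    and entropy-scaled sequence logos localize the nucleotide regions that
    drive classification; attention vectors can be mapped onto a multiple
    sequence alignment and budgeted per 16S variable region. Includes a
    synthetic amplicon generator with planted class-discriminative loci so the
    whole pipeline is testable end to end, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
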