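Package: mkftm
Title: Multiple-Kernel Fuzzy Topic Modeling for Biomedical Text
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Topic modeling for plain-text corpora built on fuzzy clustering.
    Documents are represented as bag-of-words count matrices, weighted by a
    fusion probabilistic inverse document frequency (FP-IDF) global term
    weight, de-noised with principal component analysis, and fuzzily
    clustered with multiple-kernel fuzzy c-means. The fuzzy memberships and
    the weighted matrix are converted into the probability tables of a topic
    model: P(D), P(T|D), P(D|T), P(W|D) and P(W|T). Includes a seeded
    synthetic-corpus generator with planted topics, evaluation utilities
    (Calinski-Harabasz index, corpus log-likelihood, a cost-sensitive
    discriminant classifier with stratified cross-validation) and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    mclust
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
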