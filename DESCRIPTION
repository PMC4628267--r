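Package: funmut
Title: Functional Outcome Classification of Protein Point Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies protein point mutations as loss, gain, switch, or
    conservation of function by scoring wild-type and mutant sequences against
    profile hidden Markov models built from subfamily clusters of a homolog
    alignment. Subfamilies are detected by combinatorial entropy optimization
    (with a K-means baseline and Dunn / Davies-Bouldin cluster validity
    indices), per-cluster profile HMMs are estimated with Laplace pseudocounts
    and scored by a global log-odds forward algorithm, and two logistic
    probabilities (losing the original subfamily's function, acquiring another
    subfamily's function) are combined into four confidence scores. Includes a
    subfamily-structured alignment simulator with planted variants of each
    outcome type, and evaluation utilities (confusion matrices, binary metrics
    restricted to gain/loss calls, ROC sweeps over the score cutoff, and
    transactivity labeling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
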