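Package: lotlearn
Title: Boolean Concept Complexity Across Languages of Thought and
    Neural-Network Learning Effort
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing two accounts of Boolean category
    acquisition.  The symbolic account measures the complexity of a
    category as the length of its shortest formula in a language of
    thought (LOT), a set of unary and binary logical operators applied
    to property literals; the package enumerates all operator subsets
    drawn from nine candidate connectives, filters them to functionally
    complete bases via Post's criterion, and computes exact minimal
    formula lengths for every category with a size-ordered dynamic
    program over truth tables.  The connectionist account measures the
    effort of a small feedforward network (two rectifier hidden layers,
    sigmoid output, binary cross entropy, Adam) as the mean training
    loss over all batches and epochs.  The two are joined by per-LOT
    Spearman rank correlations, with operator-level summaries and a
    surrogate-data generator for fast end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
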