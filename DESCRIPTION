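Package: svprob
Title: Probabilistic Structural Variant Discovery from Multiple Alignment Signals
Version: 0.1.0
Authors@R:
    person("svprob", "developers", email = "svprob@example.org", role = c("aut", "cre"))
Description: Detects structural variant (SV) breakpoints from paired-end
    alignments, split-read alignments and externally supplied (BEDPE) prior
    evidence. Every evidence item is converted to a pair of breakpoint
    probability intervals; intersecting evidence is clustered across one or
    more samples and calls are derived from the trimmed product (or sum) of
    the member distributions, reported with 95% credible intervals and
    maximum-likelihood breakpoint positions. Includes an idealized
    genome/alignment simulator and a truth-matching benchmark module so the
    caller can be evaluated end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Rsamtools,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
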