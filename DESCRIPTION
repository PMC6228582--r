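Package: promstrength
Title: Sequence-Based Prediction of Sigma70 Promoter Strength
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the strength of Escherichia coli sigma70 promoters from
    their -35 and -10 hexamer sequences. Position weight matrices (PWMs) are
    built from curated hexamer sets with a GC-content-aware pseudocount and
    used to score candidate hexamers; an exact score null distribution gives
    per-match p-values for filtering hits extracted from 13-nt promoter
    regions. A multiple linear regression then maps the two PWM scores to the
    natural log of normalized promoter strength, fit either by exact least
    squares or by batch gradient descent, with classical inference,
    leave-one-out cross-validation, regression diagnostics, variant-model
    comparison, and a random-promoter baseline. Ships the 18-promoter
    Anderson library training fixture and a synthetic hexamer-set generator,
    plus a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
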