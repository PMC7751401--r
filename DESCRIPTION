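Package: svensemble
Title: Consensus Structural-Variant Calling with Calibrated Phred Qualities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Merges structural-variant (SV) calls from multiple callers into
    consensus candidates by breakpoint-distance clustering, assigns each
    consensus event a Phred-encoded quality value calibrated from the
    empirical precision of its supporting-caller combination, SV type and
    size class against a truth set, and evaluates call sets with
    size-stratified precision/recall/F1, per-combination breakdowns,
    replicate concordance and cross-sample population allele frequencies.
    Includes a fully parameterised ensemble simulator (per-caller
    sensitivity, false-call rate and breakpoint jitter over a synthetic
    genome) so every stage is testable without external data, and a
    command-line interface wiring the stages into a workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    vcfR,
    igraph,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
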