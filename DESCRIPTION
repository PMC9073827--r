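Package: cptgdm
Title: Group Decision Making with Cumulative Prospect Theory over Interval Payoffs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Ranks emergency-response alternatives by multi-attribute cumulative
    prospect theory when both expert reference points and attribute outcomes are
    interval numbers. Experts' interval reference points are aggregated into a
    collective reference per criterion via similarity-based consensus weights;
    interval attribute values are converted into crisp gains and losses relative
    to the collective reference; and alternatives are scored with a piecewise
    power value function, per-criterion normalization, and rank-dependent
    decision weights built from a neo-additive probability weighting function.
    Includes a problem-document reader/writer (JSON and YAML), a seeded random
    problem generator for property testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
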