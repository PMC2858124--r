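Package: evita
Title: Early Evaluation of the Additional Therapeutic Value of New Drugs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic benefit/risk scoring of a new drug in one approved
    indication from randomized-controlled-trial (RCT) evidence. Trials are
    screened with a Jadad quality cut-off and comparator rules, classified
    into a trial setting (A1/A2/B1/B2 or N/A), scored for efficiency (result
    direction, trial count, outcome level, with a number-needed-to-treat
    strength modifier) and for the comparative adverse-event risk profile
    (CTCAE severity groups by frequency class, plus drug-interaction
    penalties). Efficiency and net risk add up to a bounded score in
    [-25, +25] presented as a color band, or an explicit "not assessable"
    verdict when no eligible trial exists. Assessment dossiers are read and
    written as YAML or JSON with a full inclusion/exclusion audit trail; a
    synthetic-dossier generator and a command-line interface are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
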