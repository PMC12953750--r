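Package: acutelang
Title: Acute-Window Analysis of Passively Sensed Smartphone Language
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing passively sensed smartphone keyboard text in
    the days surrounding a suicide-related psychiatric hospitalization.
    Segments keyboard input events into text entries, labels each entry for
    suicide-related language (a lexicon engine covering keywords, slang,
    multi-word phrases and emoji), sentiment (a pluggable scorer with a
    deterministic rule-based default) and negative self-reference, assigns
    entries to seeded topics by similarity, aggregates labels to daily
    proportions, and quantifies within-person elevations in acute windows
    before hospitalization, including window-length sensitivity ratio curves,
    time-of-day and weekday/weekend stratification, and correspondence with
    clinician-annotated event timelines. A synthetic-data generator with known
    ground truth makes every stage verifiable without access to raw text.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
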