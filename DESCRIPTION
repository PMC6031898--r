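Package: ccat
Title: Computerized Cognitive Addiction Therapy Task Battery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A headless, seedable engine for a computerized cognitive
    addiction therapy (CCAT) battery: four adaptive training tasks
    (drug-cue attention bias modification, attention control training,
    adaptive N-back, memory matrix), four scored decision-making
    assessments (delay discounting with hyperbolic k estimation, Iowa
    Gambling Task, Balloon Analogue Risk Task, drug-word Stroop),
    parameterized simulated respondents with known ground truth, and the
    two-arm pre/post trial statistics used to compare groups
    (summary-statistic F tests, chi-square, 2x2 mixed ANOVA with
    group-by-time interaction). Trial logs are JSON Lines; configuration
    is YAML; a thin command-line wrapper is included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
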