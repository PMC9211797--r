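Package: mptmem
Title: Multinomial Processing Tree Models of Recognition Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for fitting multinomial processing tree (MPT) models of
    recognition memory by maximum likelihood, with likelihood-ratio tests of
    equality restrictions, effect sizes, and noncentral chi-square power and
    sensitivity analysis.  Ships the four-states remember-know-guess model and
    the two-high-threshold multinomial process-dissociation model, each
    duplicated over an animacy factor, together with aggregate frequency
    tables reconstructed from published mean proportions, so that the full
    model-based analysis of the animacy effect on recollection and
    familiarity can be reproduced end to end.  Includes an EQN model-file
    reader/writer, a multinomial data simulator, and parameter-recovery and
    empirical-power studies that validate the estimation machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
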