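Package: viscoinfer
Title: Probabilistic Inversion, Model Ranking and Experimental Design for
    Viscoelastic Material Characterization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unnormalized information-density inference for mechanical
    characterization of soft materials. Provides forward simulation of five
    Maxwell-type (non)linear viscoelastic constitutive models under
    stress-controlled triangular loading, Jeffreys logarithmic parameter
    mapping onto the unit cube, Gaussian misfit and Monte-Carlo evidence
    estimation, posterior parameter reconstruction with marginal summaries,
    hypothesis plausibility ranking with an automatic Occam penalty, and
    optimal experimental design of the test duration by information gain.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
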