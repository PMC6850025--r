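Package: warmgrowth
Title: Progressive-Change BACIPS Analysis of Warming Effects on Fish Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting gradual, size-dependent effects of
    whole-ecosystem warming on fish body growth in a paired heated/reference
    (BACIPS) design. Includes an individual-based two-area growth simulator
    with temperature- and size-dependent growth and survey sampling,
    back-calculation of length-at-age from operculum annuli under the body
    proportional hypothesis, construction of annual response and
    heated-minus-reference difference series, Progressive-Change BACIPS
    model selection (step, linear, asymptotic, sigmoid impact-response
    curves compared by AICc weights), and community-composition analysis
    via CPUE matrices and principal coordinates analysis on Chord distance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    yaml,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
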