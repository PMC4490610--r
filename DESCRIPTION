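Package: gatestack
Title: Steady-State Models and Design-Rule Checking for Layered Bacterial Logic Gates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the forward engineering of layered genetic logic circuits
    in bacteria. Fits four-parameter Hill transfer functions to inducible-promoter
    titration data, rescales fitted devices across ribosome binding site strengths,
    and composes them into steady-state predictors for AND, OR, NIMPLY, XOR,
    half-adder and half-subtractor circuits, including plasmid copy-number
    amplification, operator-site repression, 5'-UTR hairpin penalties and
    transcription-activator competition. Also provides digital performance metrics
    and truth-table calls, a flow-cytometry population classifier, a stem-loop
    (inverted repeat) detector for 5'-UTR sequences, an executable design-rule
    checker for known genetic-context failure modes, and a synthetic-data
    generator emulating plate-reader titrations and flow-cytometry populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
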