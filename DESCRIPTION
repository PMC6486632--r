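Package: rnakin
Title: Kinetic Analysis of RNA-Mediated Enzyme Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models, fitting and diagnostics for the kinetics of RNA-mediated
    inhibition of serine hydroxymethyltransferase (SHMT1). Implements binding
    isotherms for band-shift (EMSA) titrations, IC50 inhibition curves,
    Michaelis-Menten rate laws with folate substrate inhibition, and the
    hyperbolic (partial) competitive inhibition rate law, together with a
    rapid-equilibrium species-balance solver that serves as a brute-force
    oracle for the closed-form rate law. Provides global nonlinear
    least-squares estimation with bootstrap intervals, Lineweaver-Burk
    slope/intercept replot diagnostics that classify the inhibition mechanism
    (pure competitive, pure mixed, hyperbolic competitive), synthetic-data
    generators reproducing the published experimental designs, and a
    score-combination layer for ranking predicted protein-RNA interactions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
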