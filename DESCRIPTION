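Package: tlfopt
Title: Growth-Optimal Stoichiometry of mRNA Translation Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: First-principles prediction of the growth-rate-maximizing proteome
    fractions of the core bacterial mRNA translation factors (initiation factors
    IF1-IF3, elongation factors EF-Tu, EF-Ts, EF-G, aminoacyl-tRNA synthetases,
    and release/recycling factors RF1/RF2/RF4). Models translation as a
    coarse-grained ribosome cycle whose initiation, elongation and termination
    transit times depend on factor abundances through mass-action binding
    kinetics, closes the system with a proteome-allocation constraint, and
    solves the resulting flux-maximization problem analytically (square-root
    optima from an arithmetic-geometric-mean equipartition argument) and
    numerically (brute-force landscape search). Includes a nonlinear solver for
    the ternary-complex/tRNA-charging steady state across the EF-Tu/synthetase
    expression plane, the transition-line construction, diffusion-scaled
    association-rate estimation, and predicted-versus-observed comparison
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
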