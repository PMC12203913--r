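Package: smcurtain
Title: Simulation and Analysis of Single-Molecule DNA Curtain Lesion-Search Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and analyses single-molecule DNA curtain experiments on
    DNA-lesion search and the supporting biochemistry. Provides generators for
    one-dimensional protein diffusion on flow-stretched lambda DNA with
    localization noise, lesion-engagement experiments with bypass statistics and
    right-censored dwell times, curtain binding-position snapshots, EMSA-style
    titrations and FRAP traces; kymograph rendering and single-particle
    tracking; mean-squared-displacement diffusion estimation with
    sliding-versus-hopping calls and a rotation-coupled diffusion speed limit;
    bypass-based lesion recognition-efficiency statistics and censored
    exponential residence-time fits; position histograms with percentile
    bootstrap intervals and Gaussian peak fits; depletion-corrected binding
    isotherms, steady-state SPR fits, and a coupled two-protein/DNA mass-action
    equilibrium solver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
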