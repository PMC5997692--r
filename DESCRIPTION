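Package: channelflux
Title: Transport Analysis for Artificial Water Channel Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis chain for artificial water channels
    reconstituted in lipid and block-copolymer membranes. Fits stopped-flow
    light-scattering swelling traces to osmotic water permeabilities,
    counts channels per vesicle from two-species fluorescence correlation
    spectroscopy, infers single-channel permeabilities, computes trajectory
    observables (blocked mean-squared displacement and diffusivities,
    Kabsch-superposed RMSD, tilt-angle statistics, and the collective
    diffusion permeability for single-file water transport), averages and
    integrates constant-velocity pulling force traces into potentials of
    mean force, and characterises filtration membranes (hydraulic
    permeability, concentration-polarization-corrected rejections, logistic
    molecular weight cutoff fits, and derivative pore-size distributions).
    Seeded synthetic-data generators with recorded ground truth stand in
    for the instruments and the simulation engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
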