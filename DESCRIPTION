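Package: fretburst
Title: Single-Molecule FRET Burst Analysis and Nucleosome Decompaction Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Confocal single-molecule FRET burst analysis with pulsed
    interleaved excitation (PIE/ALEX): fixed-bin photon-burst search,
    background/crosstalk/direct-excitation/gamma corrections yielding
    transfer efficiencies and stoichiometry ratios, shot-noise-constrained
    global Gaussian fitting of transfer-efficiency histograms, and two-state
    pseudo-first-order kinetic inference for time-resolved measurements such
    as poly(ADP-ribose)-induced nucleosome decompaction in droplet
    microfluidic mixers. Includes a synthetic photon-stream generator with
    known ground truth for validation, and companion tools for simulation
    trajectories (Foerster efficiencies, intermolecular contacts, WHAM
    potentials of mean force from umbrella sampling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
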