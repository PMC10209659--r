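Package: graphei
Title: Predicted Electron-Ionization Mass Spectrum Libraries from Molecular Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for GC-MS compound identification with predicted
    electron-ionization (EI) mass spectra. Molecular structures (SMILES or
    SDF) are converted to attributed graphs (adjacency, incidence, one-hot
    element and bond-type features), a message-passing neural network maps
    each graph to a unit-m/z spectrum over m/z 15-1010, predicted spectra
    are assembled into a molecular-formula-indexed library under standard
    exclusion rules (multi-component records, molecular weight over 1000 Da,
    elements outside C/O/N/B/F/P/S/Cl/Si/Br/I), and query spectra are
    matched by formula-filtered cosine-similarity ranking, with brute-force
    search and rank-percentile evaluation utilities. A fixture generator
    produces synthetic structure/spectrum pairs so the full train/build/search
    loop runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
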