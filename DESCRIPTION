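Package: lovpocket
Title: Binding-Pocket Dynamics and Vibronic Spectra of LOV-Based Fluorescent Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-simulation analysis tools linking the hydrogen-bond network
    dynamics of the flavin mononucleotide (FMN) binding pocket in LOV-based
    fluorescent proteins to their absorption spectra and Stokes shifts.
    Provides labeled H-bond distance, side-chain dihedral and chromophore-ring
    RMSD observables from multi-model PDB/XYZ trajectories; in/out side-chain
    state classification, PCA reduction and hierarchical density-based
    clustering of pocket conformations; a van der Waals pseudo-density overlap
    ("crowding") metric; vibronic absorption lineshapes from Huang-Rhys
    factors via the second-order cumulant expansion in the displaced
    harmonic oscillator formalism; ensemble and population-weighted spectra
    and Stokes-shift tables; and a synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
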