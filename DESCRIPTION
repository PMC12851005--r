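Package: rdtherm
Title: Temperature-Series Structural Analysis of a Hyperthermophile Rubredoxin
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of temperature-dependent structural change in a small
    Zn-substituted rubredoxin-like protein across a 100-393 K series of
    crystal structures and reduced molecular-dynamics trajectories. Reads and
    writes fixed-column PDB files with unit-cell metadata; detects direct and
    water-mediated hydrogen bonds and tabulates donor partner switches across
    temperature; computes Kabsch superposition RMSD, metal-site coordination
    statistics, triclinic unit-cell and grid-based van der Waals protein
    volumes, and per-residue B-factor profiles with z-score normalization;
    fits linear thermal-expansion and two-segment changepoint trends;
    classifies three-state distance trajectories, computes occupancies and
    dwell times, and estimates the enthalpy and entropy of the
    partner-exchange equilibrium by a van't Hoff fit with moving-block
    bootstrap errors. A synthetic-data module generates schematic
    rubredoxin-like structure series and three-state Markov distance
    trajectories with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr,
    pracma
Config/testthat/edition: 3
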