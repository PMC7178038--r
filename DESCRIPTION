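Package: acpstab
Title: Stability Thermodynamics and Structural Geometry of Acyl Carrier Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantitative stability analysis for small helical proteins such as
    bacterial acyl carrier proteins (ACPs). Implements per-residue
    hydrogen/deuterium exchange (HDX) thermodynamics: intrinsic random-coil
    amide exchange rates with sequence-context corrections, exponential
    peak-decay fitting, protection free energies, hyperprotection detection and
    EX1/EX2 regime diagnosis from paired-pD measurements. Also provides
    two-state chemical-denaturation analysis by the linear extrapolation model,
    two-state differential scanning calorimetry fits, a global-vs-local
    unfolding regime classifier, coordinate-level geometry (ensemble
    superposition and RMSD-to-mean, pocket-entrance distances, side-chain
    contacts, salt bridges, charge census and isoelectric point, RDC Q-factor),
    and seeded synthetic-data generators for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
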