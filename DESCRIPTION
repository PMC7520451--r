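Package: suctionpower
Title: Suction-Feeding Kinematics, Muscle Strain and Expansion Power from
    Marker-Based X-ray Motion Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for marker-based X-ray motion studies of
    suction feeding in fishes. Estimates per-frame rigid-body transforms of
    marked bones from implanted marker trajectories (orthogonal least-squares
    fit), decomposes relative bone motion in joint coordinate systems with a
    zyx Euler sequence, measures axial-muscle strain and strain rate from
    intramuscular marker chains (fluoromicrometry) and cranial-muscle length
    from bone-attached fiber landmarks, reconstructs a dynamic endocast of the
    mouth cavity as a per-frame three-dimensional alpha-shape volume, and
    combines the volume rate of change with an intra-oral pressure trace into
    instantaneous mouth-expansion power. Includes zero-phase Butterworth
    filtering of kinematic signals, a seeded synthetic-strike generator with
    analytically known ground truth for validation, readers and writers for
    the tabular formats involved, and per-strike and per-individual summary
    reporting.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
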