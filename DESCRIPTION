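Package: ssxtools
Title: Serial Synchrotron Crystallography Simulation and Snapshot Merging
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A self-contained toolkit for room-temperature serial synchrotron
    crystallography (SSX) with microcrystals flowing in a capillary across a
    microfocus beam. Provides closed-form beamline and microfluidics
    calculations (wavelength, Poiseuille flow, transit time, Reynolds number,
    simplified absorbed dose, detector-edge resolution, acquisition budgets),
    a synthetic still-diffraction frame simulator with known ground truth
    (uniform random orientations, Poisson crystal arrivals, Wilson-distributed
    structure factors, excitation-error partiality, water-ring background,
    azimuthal arc smearing), and the full snapshot processing chain: gradient
    peak finding, known-cell still indexing with per-frame cell refinement,
    spot prediction and annulus-background integration, Monte Carlo merging
    into unique reflections, and half-set quality statistics (R_split, CC1/2,
    CC*, I/sigma, completeness, redundancy, Wilson B) with convergence
    analysis versus the number of indexed patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
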