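Package: pentapocket
Title: Binding-Pocket Dynamics Descriptors for Pentameric Ligand-Gated Ion Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric descriptors of orthosteric binding-pocket dynamics in
    homopentameric ligand-gated ion channel extracellular domains, computed
    from molecular-dynamics trajectories. Implements per-frame hydrogen-bond,
    water-bridge and cation-pi detectors with occurrence statistics, a
    convex-hull "atomic cage" water-occupancy and pocket-volume measure, a
    Loop C orientation angle, subunit-assembly metrics (backbone RMSD,
    per-loop RMSF, intersubunit contact maps, planar intra- and interpocket
    centroid distances, push-pull distance correlations), and the two
    metadynamics collective variables used for ligand ejection (binding-site
    COM distance and a rational switching-function solvation coordination).
    Ships a C5-symmetric synthetic pentamer trajectory generator with an exact
    ground-truth ledger for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
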