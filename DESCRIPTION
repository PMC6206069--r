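Package: soapshift
Title: SOAP Kernel Regression of NMR Chemical Shifts in Molecular Solids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Machine-learned prediction of isotropic NMR chemical shieldings
    for atoms in periodic organic crystals (H, C, N, O). Local atomic
    environments are encoded as smooth-overlap-of-atomic-positions (SOAP)
    power-spectrum descriptors and regressed with Gaussian-process
    (kernel ridge) models built on a weighted combination of kernels at
    several cutoff radii. Includes training-set curation by farthest point
    sampling, removal of symmetry-equivalent environments and
    cross-validation outlier pruning; shielding-to-shift referencing; and a
    chemical-shift-driven NMR crystallography protocol that ranks candidate
    polymorph structures against assigned experimental shifts. A synthetic
    crystal generator and shielding oracle make the whole pipeline testable
    without electronic-structure calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
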