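Package: npstereo
Title: Structure and Absolute-Configuration Assignment Tools for Natural Products
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computational procedures used to assign structures and absolute
    configurations of small-molecule natural products: molecular-formula
    arithmetic for validating high-resolution ESI mass spectra (monoisotopic
    masses, adduct m/z with electron-mass correction, ppm errors, degrees of
    unsaturation, isotope-pattern simulation and a chlorine M+2 signature
    test); Boltzmann weighting of conformer ensembles from relative Gibbs
    free energies, with an energy cutoff and dihedral-class mixture
    reweighting; electronic circular dichroism (ECD) spectrum construction
    from computed transitions via Gaussian band shapes, ensemble averaging,
    UV shifting, peak-normalised scaling and sign-sensitive spectral
    comparison for enantiomer discrimination; and modified Mosher ester
    delta-delta analysis for carbinol stereocenter calls.  A synthetic-data
    module generates conformer ensembles, noisy experimental-style spectra
    and Mosher shift tables with known ground truth so that every stage of
    the pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
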