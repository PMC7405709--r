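Package: eyefem
Title: Biomechanical Finite-Element Simulation of Myopic Laser Refractive
    Surgery and Induced Wavefront Aberrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the corneal biomechanical response to conventional
    myopic laser refractive surgery (LASIK) in a whole-eye nonlinear
    finite-element model. The eye globe is built as a parametric
    hexahedral shell (Gullstrand-style cornea bonded to sclera), a hinged
    lamellar flap is cut as a crack, a Munnerlyn ablation profile is
    subtracted from the stromal bed, and the model is inflated by
    intraocular pressure with incompressible Ogden hyperelastic materials.
    Corneal surface displacement fields are converted to optical path
    difference and decomposed into Zernike wavefront aberrations, so that
    the biomechanically induced defocus (hyperopic shift), spherical
    aberration, coma and trefoil can be quantified across refractive
    corrections, pressures, treatment decentrations, pupil sizes and
    tissue stiffness cases. Includes closed-form shell-inflation oracles
    and synthetic displacement-field generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
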