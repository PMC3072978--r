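Package: poresim
Title: Current Distribution Models for Singularity-Induced
    Micro-Electroporation Devices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Steady-state electric field simulators for singularity-induced
    micro-electroporation devices, in which two coplanar electrodes separated
    by a nanometre-scale insulator generate locally diverging electric fields
    at small applied voltages.  Implements a non-dimensional primary current
    distribution model of a micro-electroporation channel (Laplace equation
    with equipotential electrodes) and a dimensional secondary current
    distribution model with Butler-Volmer electrode kinetics for inert
    platinum electrodes in water.  Provides graded structured meshing toward
    the insulator corner singularities, a conservative five-point
    finite-volume Laplace solver with mixed Dirichlet, zero-flux and
    nonlinear kinetic flux boundary conditions, boundary current integration,
    cell power accounting, parametric sweep drivers, and a plain-text
    configuration interface with CSV output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
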