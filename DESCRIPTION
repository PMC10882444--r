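Package: dimerspec
Title: Spin-Hamiltonian Simulation and Fitting for Exchange-Coupled
    Bimetallic Centres
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the magnetic spectroscopy of exchange-coupled
    bimetallic centres such as Fe(III)-Mn(III) and Fe(III)-Mn(IV) cores.
    Builds and diagonalizes Heisenberg exchange spin Hamiltonians with
    Zeeman, zero-field-splitting and nuclear hyperfine terms; maps tensors
    between the coupled and site representations with spin-projection
    coefficients; simulates powder cw-EPR spectra of the coupled doublet
    with 55Mn hyperfine structure at arbitrary microwave frequency;
    computes effective g-values of Kramers doublets from zero-field
    splitting; fits exchange couplings from temperature series and
    microwave power-saturation (Orbach) data; and simulates variable-field
    57Fe Moessbauer spectra of coupled dimers, optionally diagonalizing
    the 55Mn nuclear spin together with the electronic system so that the
    second nucleus perturbs the iron-site spin expectation at low applied
    field.  Includes a seeded synthetic-data generator for every supported
    experiment and structural descriptors (tau5, metal displacement from a
    ligand plane) for five-coordinate sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
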