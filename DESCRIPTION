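Package: stemrit
Title: Delayed Dynamical Modelling of Cancer Stem Cell Radioimmunotherapy
    with Hypoxia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates radioimmunotherapy (RIT) of tumors driven by cancer
    stem cell (CSC) plasticity. Couples a delayed dynamical system for CSCs,
    differentiated cancer cells, Wnt-beta-catenin signalling and microRNAs to
    a linear-quadratic radiobiology stack for internally administered
    radionuclides (90Y, 131I, 177Lu, 225Ac): biexponential uptake/clearance
    dose-rate kinetics, dose-protraction factor, relative effectiveness,
    biologically effective dose, oxygen enhancement ratio, surviving fraction
    and Poisson tumor control probability. Includes a two-dimensional
    Michaelis-Menten oxygen reaction-diffusion solver for hypoxia, and a
    local one-at-a-time sensitivity analysis with normalized elasticity
    indices. The delay integrator is a fixed-step fourth-order Runge-Kutta
    method with cubic Hermite dense output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    yaml
Config/testthat/edition: 3
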