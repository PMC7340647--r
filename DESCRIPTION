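Package: nozzlelbm
Title: Lattice Boltzmann Simulation and Analysis of Transitional Flow in the
    FDA Benchmark Nozzle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale direct numerical simulation pipeline for transitional
    flow in the FDA sudden-expansion nozzle benchmark. Provides diffusive-scaling
    conversion between physical and lattice units, an analytic parametric nozzle
    geometry with voxelization and sub-cell wall distances, a D3Q19
    multiple-relaxation-time lattice Boltzmann solver with Bouzidi curved-wall,
    parabolic-inflow and extrapolation-outflow boundary conditions, turbulence
    characterization (Reynolds decomposition, turbulent kinetic energy, Welch
    spectra on a Strouhal axis, Kolmogorov microscales and resolution-quality
    ratios), quantitative comparison against PIV-style reference profiles, and
    synthetic-data generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
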