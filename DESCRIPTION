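Package: lipidperm
Title: Umbrella-Sampling Free-Energy Profiles and Bilayer Permeability via the Inhomogeneous Solubility-Diffusion Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing potential-of-mean-force (PMF) profiles of
    amphiphiles along the lipid-bilayer normal from umbrella-sampling window
    data (weighted histogram analysis method with convergence diagnostics and
    split-half uncertainties), estimating depth-resolved local diffusion
    coefficients from restraint-force autocorrelation functions, and combining
    both into membrane resistance profiles and permeability coefficients under
    the inhomogeneous solubility-diffusion model with selectable free-energy
    reference conventions. Includes a synthetic-data generator with known
    ground truth (parametric PMF families, Ornstein-Uhlenbeck force series,
    idealized membrane frames), membrane descriptors (area decomposition,
    deuterium order parameters, orientation, chain elongation, hydrogen-bond
    counts), plain-text readers and writers for window time series and depth
    profiles, and a one-call pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
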