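Package: methanox
Title: Methane Oxidation Analysis for Stratified Lake Water Columns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying microbial methane oxidation in stratified
    (meromictic) lake water columns from stable carbon isotope and
    concentration data. Implements delta-notation arithmetic on the VPDB
    scale, closed-system Rayleigh fractionation fitting of apparent
    fractionation factors, back-calculation of dissolved methane from
    headspace-equilibrated samples via Bunsen solubility coefficients,
    potential methane-oxidation rate estimation from 13CH4-tracer incubation
    time series of delta13C-DIC, turbulent diffusive flux and
    electron-equivalent redox budgeting across the oxycline, threshold- and
    gradient-based redox/methane zonation of profiles, and a two-isotope
    steady-state reaction-diffusion generator of synthetic water columns and
    incubations for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
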