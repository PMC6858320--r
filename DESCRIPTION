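Package: myoglide
Title: Gliding-Assay Simulation and Kymograph Analysis of Myosin-Driven
    Actin Depolymerization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic simulation and analysis of in vitro actin gliding
    assays in which surface-bound myosin motors both propel filaments and,
    through force-dependent (catch-bond) attachment near the barbed end,
    enhance barbed-end depolymerization. Simulates single filaments gliding
    over beds of motors immobilized on glass or anchored in a fluid supported
    lipid bilayer, renders synthetic TIRF movies and kymographs with
    realistic pixelation, blur and noise, and provides the full measurement
    chain used on such data: kymograph flattening, edge tracking, sliding
    velocity and elongation estimation, linear barbed-end kinetics fitting
    (k_on, k_off, critical concentration) with bootstrap uncertainties, FRAP
    recovery fitting with the Soumpasis relation, and fluorescence-to-surface
    density calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
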