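Package: biletox
Title: Mechanistic Simulation of Bile Acid-Mediated Drug-Induced Liver Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative systems pharmacology simulator for drug-induced
    liver injury mediated by inhibition of hepatic bile acid transporters.
    Couples a minimal physiologically based pharmacokinetic model of a drug
    and its metabolites (with saturable hepatic uptake, autoinduction and
    biliary clearance) to an enterohepatic bile acid recirculation model
    (chenodeoxycholic and lithocholic acid species; BSEP, NTCP and
    basolateral transport with competitive or noncompetitive inhibition),
    an ATP-decline hepatotoxicity model with Hill-type synthesis inhibition
    and delayed bile acid sensing, hepatocyte-loss and serum ALT/bilirubin
    biomarker dynamics, and seeded virtual populations for incidence
    estimation. Includes vesicle-assay IC50 analysis, parameter fitting
    from concentration-time data, and synthetic data generators for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
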