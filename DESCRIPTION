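Package: phycodiesel
Title: Microalgal FAME Profiling, Mutant Screening and Biodiesel Property
    Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative analysis toolkit for microalgal biodiesel feedstock
    development by random mutagenesis. Parses and validates compositional
    fatty-acid methyl ester (FAME) tables, summarizes saturation classes
    (SFA/MUFA/PUFA) and the average degree of unsaturation (ADU), estimates
    biodiesel fuel properties (kinematic viscosity, density, cloud point,
    cetane number, iodine value, higher heating value, long-chain saturated
    factor and cold filter plugging point) from empirical linear regressions
    on ADU, and checks them against ASTM D6751 and EN 14214 limits. Also
    covers growth-curve kinetics (OD-to-dry-weight calibration, specific
    growth rate, biomass and lipid productivity), plasma-mutagenesis
    screening arithmetic (mortality rate, optimal exposure selection, mutant
    ranking), spectrophotometric assay calibration (pigments, total lipid,
    carbohydrate, protein and Nile-red triglyceride standard curves), and a
    seeded synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
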