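Package: neonoxy
Title: Gas Exchange, Regional Oximetry and Cerebral Autoregulation Analysis
    for Neonatal Acute Lung Injury Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physiological computation pipeline for neonatal acute-lung-injury
    oximetry studies. Computes oxygen-transport indices (alveolar gas equation,
    alveolar-arterial difference, P/F ratio, oxygen content), estimates
    intrapulmonary shunt fraction and ventilation-perfusion displacement from
    stepwise FiO2-SaO2 observations, derives regional fractional oxygen
    extraction from near-infrared spectroscopy with risk flagging and arterial
    saturation binning, classifies cerebral autoregulation impairment against a
    configurable nomogram, fits single-compartment respiratory mechanics, and
    scores lung-ultrasound aeration. Includes a synthetic piglet-cohort
    generator with exported ground truth for parameter-recovery validation of
    every estimator, plus tidy readers, writers and an end-to-end report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
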