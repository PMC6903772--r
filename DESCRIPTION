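Package: zntrace
Title: Enriched Stable-Isotope Source Tracing of Zinc in Soil-Fertilizer-Plant Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for enriched stable-isotope source tracing of zinc with
    single-collector quadrupole and multicollector ICP-MS. Implements the
    two-source isotope mass-balance mixing model that partitions plant Zn
    between soil-available Zn and an (organic) fertilizer, abundance/ratio
    algebra for the five stable Zn isotopes, mass-bias correction of raw
    ratio measurements by standard-sample-standard bracketing with a
    power-law fractionation model, a synthetic ICP-MS measurement generator
    (instrument noise, mass-bias drift, replicate schemes, matrix
    interference), source-resolution statistics (isotope enrichment,
    experimental precision, statistically distinguishable ratios, smallest
    detectable source contribution), Bland-Altman instrument comparison,
    and isotope-dilution spike planning for indirect soil labeling.
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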