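Package: rrfkit
Title: Day-of-Analysis Relative Response Factors for Extractables and
    Leachables Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the day-of-analysis relative response factor (RRF)
    workflow used in nontargeted chemical characterization of medical-device
    extractables and leachables. Computes compound responses under the common
    mass-spectrometric quantitation models (total ion, base peak, extracted
    ion, and extracted compound chromatograms), estimates RRFs as weighted
    least-squares slopes over qualified dynamic ranges with injection-RSD and
    linearity acceptance filters, summarizes RRF populations across
    instrumental calibrations, derives uncertainty factors (UF) and adjusted
    analytical evaluation thresholds (AET), and semiquantitates nontarget
    extractables through surrogate RRFs. Includes elemental-formula and
    isotopologue-envelope arithmetic for electrospray adduct ensembles, and a
    seeded simulator of multi-day calibration campaigns (adduct-ratio drift,
    response nonlinearity, replicate noise, internal standards) so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
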