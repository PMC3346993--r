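Package: trical
Title: Second-Order Calibration of HPLC-DAD Data by Trilinear Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for second-order (three-way) calibration of liquid
    chromatography with diode-array detection. Implements trilinear
    decomposition of elution-time x wavelength x sample data cubes by
    alternating least squares (PARAFAC-ALS, with optional nonnegativity)
    and by self-weighted alternating trilinear decomposition (SWATLD),
    chemical-rank estimation via the core consistency diagnostic
    (CORCONDIA), concentration prediction exploiting the second-order
    advantage, and net-analyte-signal figures of merit (sensitivity,
    selectivity, limit of detection). Includes a synthetic-data generator
    that emulates overlapped chromatographic peaks with broadband UV
    spectra and uncalibrated interferents, plus delimited-text input and
    output for data cubes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
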