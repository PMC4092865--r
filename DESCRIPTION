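Package: erbbcombo
Title: Kinetic Modelling of Anti-HER2 Combination Therapy and Receptor
    Co-Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mass-action kinetic modelling of HER2/HER3 receptor
    dimerisation under trastuzumab, pertuzumab and combination treatment,
    with downstream PI3K/AKT and Ras/RAF/MEK/ERK signalling. Computes
    percent inhibition of pAKT and pERK relative to drug-free controls,
    scans inhibition against the HER3/HER2 co-expression ratio, and
    compares cell-line presets against reference inhibition observations.
    Also provides the accompanying differential-expression toolkit
    (fold changes, Student's t-test on log2 intensities, volcano
    categories, three-set Venn counts, pathway heatmap matrices) and a
    seeded synthetic-data generator for expression matrices with planted
    fold changes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
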