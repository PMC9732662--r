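Package: cowflow
Title: Lumped-Parameter Circle of Willis Hemodynamics with Personalized Windkessel Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates blood flow through the circle of Willis with a
    lumped-parameter (electrical-analog) arterial network: 18 cerebral and 15
    systemic segments, a prescribed aortic inflow, and three-element Windkessel
    (WK3) outlets. Provides a three-step per-patient calibration of peripheral
    resistance and arterial compliance from cuff blood pressure and
    transcranial Doppler (TCD) velocities, a TCD observation model for the nine
    standard insonation sites, agreement statistics (two-way random consistency
    ICC with exact F confidence intervals, base-10 log Bland-Altman limits of
    agreement, Wilcoxon paired tests, subgroup stratification), and a virtual
    aneurysmal subarachnoid hemorrhage cohort generator with anatomical
    variants, vasospastic narrowing and measurement noise for end-to-end
    validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    igraph,
    jsonlite,
    Matrix,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
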