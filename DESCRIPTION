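Package: nmjquant
Title: Quantal Analysis and Homeostatic Plasticity Metrics for NMJ
    Electrophysiology and Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis stack for bi-directional presynaptic homeostatic
    plasticity at the Drosophila neuromuscular junction: quantal content from
    miniature and evoked postsynaptic responses, readily-releasable pool (RRP)
    estimation by cumulative-EPSC back-extrapolation from 60 Hz trains,
    release-probability metrics (P_train, paired-pulse ratio, depression decay
    constants), calcium-transient dF/F analysis of line-scan imaging, and
    optical action-potential waveform metrics from Archaerhodopsin voltage
    imaging. Includes stochastic ground-truth simulators (binomial
    vesicle-depletion release model, Poisson miniature-event trains, calcium
    line scans with bleaching, Arch fluorescence traces with photobleach
    decay) used to validate every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    signal,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
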