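Package: chlamycycle
Title: Timer and Sizer Control of the Chlamydomonas Cell Cycle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Simulation and single-cell analysis of cell-cycle control in the
    green alga Chlamydomonas reinhardtii under arbitrary light schedules.
    Implements light-limited exponential volume growth, an interdivision
    timer (division-phase entry when accrued growth-rate-times-time reaches
    a fixed constant), a commitment sizer (a cell must double its volume in
    the light before it can ever divide), and a mitotic sizer (the
    final-to-initial volume ratio sets the number of daughters produced by
    multiple fission). Includes a trajectory-analysis pipeline that segments
    measured volume time series, estimates per-light-period growth rates and
    the timer products, and summarises cohorts; a contour-based cell
    volumetry module that estimates volume from single-cell micrographs by
    rotating the cross-section about its long axis; and a seeded synthetic
    data generator producing noisy cohorts and test images with ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    EBImage
Suggests:
    withr,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
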