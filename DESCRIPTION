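Package: spabalance
Title: Spontaneous Physical Activity from Load-Cell Weighing Balances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for home-cage spontaneous physical activity
    (SPA) recorded with three-load-cell weighing balances. Reads raw
    four-column signal streams, fits per-cell linear calibrations with fit
    diagnostics, filters outliers, bins samples into wall-clock minutes, and
    computes the minute-level sum and mean of absolute weight changes
    (SWC/MWC) together with their dispersion (SD-WC/CV-WC). Applies per-day
    baseline-bias correction, quartile-based classification of minutes into
    four activity domains, hourly/daily/experiment time-in-domain tallies,
    actogram-style heat maps, nadir/acrophase extraction and trapezoidal
    area-under-curve summaries. Includes a physics-grounded simulator (static
    three-point load distribution, circadian activity contrast, sampling
    jitter, outlier spikes, per-day baseline drift) so the whole pipeline can
    be exercised and validated without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
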