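Package: resthrv
Title: Resting Heart Rate Variability from Wearable Interbeat Intervals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning timestamped interbeat-interval (IBI) recordings
    from consumer wearables into resting heart-rate-variability (HRV) metrics,
    and for relating those metrics to repeatedly measured health variables in
    intensive longitudinal designs. Implements nocturnal windowing, 5-minute
    segmentation with completeness and movement screening, spurious-beat
    filtering, cubic-spline tachogram interpolation, time-domain (RMSSD, SDNN)
    and Welch-based frequency-domain (HF, LF, VLF) metrics; two-level maximum
    likelihood estimation of within-person and between-person correlations
    with between-level age and gender adjustment, biserial correlations for
    binary variables, variance-components intraclass correlations; Monte Carlo
    power analysis for two-level correlation tests; and seeded synthetic-data
    generators for IBI series and two-level panels with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
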