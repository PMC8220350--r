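Package: rpclim
Title: Projecting Raynaud's Phenomenon Prevalence and Severity Under
    Climate Change Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how global warming alters the worldwide burden of
    Raynaud's phenomenon. Calibrates a linear model of population prevalence
    against cold-season (November-March) mean temperature from published
    survey tables, fits a log-link Poisson model of daily attack counts on
    temperature from n-of-1 symptom diaries by iteratively reweighted least
    squares, and projects both models onto gridded daily temperature fields
    (CF-convention NetCDF) for a baseline and a future Christmas under the
    four Representative Concentration Pathway (RCP) scenarios. Includes
    synthetic generators for all three input kinds with known ground truth,
    so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ncdf4,
    geosphere,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
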