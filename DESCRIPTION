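Package: oncocap
Title: Needs-Based Estimation of Cancer Control Human Resources and
    Infrastructure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A planning pipeline for estimating the human resources,
    oncology beds, and radiotherapy equipment required for cancer control
    in a country, state, or city, and for comparing requirements against
    an availability inventory. National cancer incidence is extrapolated
    to sub-national geographies by population share, converted into
    per-modality treatment demand (surgery, chemotherapy, radiotherapy)
    and in-patient bed-days using per-site treatment fractions and
    average lengths of stay, and then into specialist, ward-staffing and
    equipment requirements using ratio-based norms. Packaged reference
    tables reproduce a published needs assessment for Uttar Pradesh,
    India, and a synthetic-scenario generator supports testing and
    sensitivity analysis without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
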