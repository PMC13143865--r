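Package: vascage
Title: Sex-Stratified Vascular Age Estimation and Cardiovascular Risk
    Validation via the Klemera-Doubal Method
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates biological vascular age from non-invasive vascular
    biomarkers (brachial-ankle pulse wave velocity, ankle-brachial index,
    mean arterial pressure) by combining z-score standardization, principal
    component analysis, and the Klemera-Doubal biological-age estimator,
    fitted separately by sex on a healthy training population. Computes the
    normalized cardiovascular age acceleration eta = (CA - BA)/CA, expands
    the marker panel greedily with metabolic and inflammatory biomarkers
    using a bootstrap odds-ratio-per-SD criterion on a case-control split,
    and validates eta against incident cardiovascular disease with Cox
    proportional-hazards models, log-rank tests, restricted cubic splines,
    and Jonckheere-Terpstra trend tests. Includes a seeded synthetic-cohort
    generator with latent vascular-aging acceleration and proportional-
    hazards event times, so the full pipeline is testable without access to
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    stats,
    survival,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
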