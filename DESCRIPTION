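Package: imkfit
Title: Integrated Microdosimetric-Kinetic Modelling of Cell Survival in
    Modulated Radiation Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing clonogenic cell survival under intensity
    modulated radiation fields with the integrated microdosimetric-kinetic
    (IMK) model. Represents arbitrary temporal dose-delivery schedules and
    evaluates targeted-effect lethal lesions with the Lea-Catcheside
    dose-protraction factor, adds signal-mediated non-targeted (bystander)
    killing for in-field and out-of-field cell populations, estimates the
    sub-lethal damage repair rate and the quadratic dose coefficient from
    split-dose recovery curves, fits the remaining parameters by random-walk
    Metropolis MCMC with 95.4% predictive bands, and compares cell-migration
    versus reduced-damage-yield explanations of in-field radio-resistance.
    Includes a synthetic-data generator emulating single-dose, split-dose and
    dose-rate-regimen clonogenic experiments for fibroblast-like and
    prostate-carcinoma-like cell lines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
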