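Package: contactiiv
Title: Intra-Individual Variability in Longitudinal Contact-Survey Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-step analysis of intra-individual variability (IIV) in
    social-contact counts from longitudinal survey panels. A negative
    binomial mixed model (log link, NB2 variance) defines each
    participant's expected non-household contact level; Pearson residuals
    from that fit are summarised per person by their within-person
    standard deviation (riSD), which is then modelled with weighted
    Gamma log-link regressions to estimate mean ratios across
    sociodemographic groups and within-person paired windows
    (pre/post first vaccination, strong/weak policy stringency).
    Includes a synthetic contact-survey generator with an injectable
    window-labelled dispersion signal and a brute-force oracle for the
    implied riSD ratio, so the whole pipeline is testable without
    access to restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmmTMB,
    jsonlite,
    splines,
    stats,
    utils,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
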