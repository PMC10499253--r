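Package: scdproj
Title: Counterfactual Projection of Treatment Impact on Sickle Cell Disease Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A sequential multi-cohort model that projects the
    population-level burden of sickle cell disease (deaths, stroke,
    pulmonary hypertension, chronic kidney disease, life-years) over a
    20-year horizon under two counterfactual worlds: with and without the
    availability of a haemoglobin-raising disease-modifying treatment.
    Treatment uptake follows a logistic adoption and diffusion curve or an
    explicit treated-patient schedule; patient-level haemoglobin response is
    simulated from a normal distribution and binned into responder classes;
    lifetime complication prevalences are annualised under a constant-hazard
    convention and attenuated by response-stratified relative risks. Includes
    one-way deterministic sensitivity (tornado) analysis, tidy accessors,
    ggplot2 visualisations, delimited-table writers and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
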