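Package: idmproj
Title: Illness-Death Model Projections of Chronic Disease Prevalence
    Under Epidemic Incidence Shocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for projecting the prevalence of a chronic, remitting
    disorder with a discrete-time three-state illness-death model
    (susceptible, diseased, dead).  Fits smooth age-time trend surfaces to
    incidence and prevalence estimates, constructs a two-group mortality
    model from overall mortality and a declining mortality-risk ratio,
    estimates remission by inverting the prevalence-odds recursion,
    decomposes a weekly epidemic incidence series into Gaussian waves
    delineated by their full width at half maximum, superimposes
    parametric incidence shocks on the baseline incidence, and runs
    sex-specific cohort projections of case counts and prevalence over a
    grid of shock scenarios.  Includes a synthetic-data generator that
    produces model-consistent inputs with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
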