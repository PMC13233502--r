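Package: psmcea
Title: Partitioned Survival Cost-Effectiveness Model for Ibrutinib-Venetoclax
    in Relapsed/Refractory Mantle Cell Lymphoma
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state (progression-free, progressed, dead) partitioned
    survival model comparing ibrutinib plus venetoclax against ibrutinib plus
    placebo in relapsed or refractory mantle cell lymphoma, from the Chinese
    and United States healthcare perspectives. Provides parametric survival
    extrapolation with AIC/BIC model selection and Royston-Parmar spline
    alternatives, Guyot-style reconstruction of pseudo individual patient data
    from digitized Kaplan-Meier curves, discounted cost/QALY accrual with
    country-specific price lists, one-way and probabilistic sensitivity
    analyses with moment-matched gamma/beta distributions, cost-effectiveness
    acceptability curves, price-reduction scenario analyses and price-threshold
    searches. Ships the full published parameter set as editable CSV tables
    and a synthetic-data generator for right-censored survival data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    flexsurv
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
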