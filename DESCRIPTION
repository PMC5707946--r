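Package: greycast
Title: Grey GM(1,1) Forecasting for Short Annual Time Series
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Grey system forecasting with the even GM(1,1) model for short,
    uncertain annual time series such as pollutant emission records. Provides
    first-order accumulated generating operations and their inverse, the grey
    strengthening buffer operator for shock-distorted monotone sequences,
    least-squares estimation of the development coefficient and grey action
    quantity, optimization of the initial condition of the time-response
    function by minimizing the sum of squared relative simulation errors,
    model-adequacy diagnostics (average relative error and grey absolute
    correlation degree with accuracy grades), out-of-sample forecasting, and
    seeded synthetic-series generators for parameter-recovery studies. Ships
    the Three Gorges Reservoir Area wastewater emission series (2008-2014) as
    a worked example together with an end-to-end reproduction pipeline and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
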