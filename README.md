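# greycast

Grey GM(1,1) forecasting for short annual time series.

Environmental planners routinely need forecasts from records that are far
too short for classical time-series models: five to ten annual values of a
pollutant emission volume, positive, noisy, and driven by mechanisms
nobody can write down. Grey system theory targets exactly this
"small sample, poor information" regime, and its workhorse — the even
GM(1,1) model — needs nothing beyond the series itself. greycast is a
complete implementation for analysts working with such data: the model,
the grey strengthening buffer operator for shock-distorted records,
initial-condition optimization, adequacy diagnostics with accuracy
grades, seeded synthetic generators for method checks, and a small CLI.

## The model

For a non-negative series `x⁰(1..n)` (n ≥ 4), form the accumulated series
`x¹(k) = Σ_{j≤k} x⁰(j)` and its consecutive-neighbour means
`z¹(k) = (x¹(k) + x¹(k−1))/2`. The grey difference equation

    x⁰(k) + a·z¹(k) = b,   k = 2..n

is solved for the development coefficient `a` and grey action quantity `b`
by least squares. The whitenized equation's time response

    x̂¹(k) = (C − b/a)·e^(−a(k−1)) + b/a

is differenced back to the original scale,

    x̂⁰(k) = (1 − eᵃ)(C − b/a)·e^(−a(k−1)),

which also extrapolates to forecasts (`k > n`; one-step ratio `e^(−a)`).
Instead of forcing the initial condition `C` through the first
observation, `gm11()` by default chooses the `C` minimizing the sum of
squared relative simulation errors — a convex quadratic with a
closed-form optimum. Adequacy is judged by the average relative error
`Δ̄` and the grey absolute correlation degree `η`, each graded I–IV.

## Worked example

The package ships the Three Gorges Reservoir Area wastewater emission
records, 2008–2014. The industrial series is first stabilised with the
strengthening buffer operator (its raw record understates the true
decline), kept at the conventional 2-decimal reporting precision, then
fitted and extrapolated:

```r
library(greycast)

w1 <- round_display(strengthen_buffer(three_gorges_series("W1_raw")))
#> Warning: series 'W1_raw' is not monotone ...   (it turns upward in 2013-14)

fit <- gm11(w1)
fit
#> GM(1,1) fit for series 'W1_raw' (n = 7)
#>   development coefficient a: 0.181
#>   grey action quantity   b: 6.338
#>   initial condition      C: 5.5818 (optimized)
#>   one-step change e^(-a) - 1: -16.6%

gm11_diagnostics(fit)
#> GM(1,1) adequacy diagnostics
#>   average relative error: 0.0658 (grade III)
#>   grey correlation degree: 0.9998 (grade I)

predict(fit, h = 6)
#> GM(1,1) forecast for 'W1_raw' [10^8 tons]
#>  year value
#>  2015  1.64
#>  2016  1.37
#>  2017  1.14
#>  2018  0.95
#>  2019  0.79
#>  2020  0.66
```

Read: industrial wastewater emissions are contracting about 16.6% per
year; the fit tracks the observed window with a 6.6% mean relative error
(adequate, grade III) and near-perfect geometric similarity (η ≈ 1,
grade I), and the extrapolation reaches 0.66×10⁸ tons by 2020. The other
three streams (`W2` domestic, `W3` oily from ships, `W4` domestic from
ships) fit without buffering; `reproduce_three_gorges()` runs all four
end to end and checks every published figure of the case study:

```r
rep <- reproduce_three_gorges()
all(rep$pass)
#> [1] TRUE
```

A thin command-line wrapper is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","greycast.R",package="greycast"))') reproduce
#> 79/79 reproduction checks pass
```

with subcommands `fit`, `forecast`, `diagnose`, `synth`, `reproduce`.

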