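---
title: "Grey GM(1,1) forecasting: model, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grey GM(1,1) forecasting: model, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greycast)
```

## The problem greycast addresses

Annual environmental records — pollutant emission volumes, discharge
totals, resource use — are often *short* (five to ten points), *positive*,
and driven by socioeconomic mechanisms too entangled to model
structurally. Classical time-series machinery (ARIMA, exponential
smoothing with estimated states) is data-hungry for such series; grey
system theory was developed precisely for this "small sample, poor
information" regime. greycast implements the workhorse of that theory,
the even GM(1,1) model, together with the preprocessing and adequacy
checks practitioners use around it, with the Three Gorges Reservoir Area
wastewater emission records (2008–2014) as the worked example.

## The even GM(1,1) model

Let $x^{(0)} = (x^{(0)}(1), \dots, x^{(0)}(n))$ be a non-negative series,
$n \ge 4$. The first-order accumulated generating operation (1-AGO)
produces $x^{(1)}(k) = \sum_{j \le k} x^{(0)}(j)$, and the
consecutive-neighbour mean sequence is
$z^{(1)}(k) = \tfrac12\,(x^{(1)}(k) + x^{(1)}(k-1))$, $k = 2..n$.
The grey difference equation

$$x^{(0)}(k) + a\,z^{(1)}(k) = b, \qquad k = 2..n,$$

is solved for the *development coefficient* $a$ and *grey action
quantity* $b$ by ordinary least squares (`gm11()` uses a QR
factorisation; the closed-form normal equations are verified against it
term by term in the test suite). The whitenized equation
$\mathrm{d}x^{(1)}/\mathrm{d}t + a x^{(1)} = b$ has time response

$$\hat x^{(1)}(k) = \left(C - \tfrac{b}{a}\right) e^{-a(k-1)} + \tfrac{b}{a},$$

with initial condition $C$ on the accumulated scale; first differencing
(the inverse AGO) restores the original scale,

$$\hat x^{(0)}(k) = (1 - e^{a})\left(C - \tfrac{b}{a}\right) e^{-a(k-1)},
  \qquad k \ge 2.$$

Forecasts extrapolate the same expression beyond $k = n$; consecutive
restored values always have the ratio $e^{-a}$, so $a > 0$ means decay
and $a < 0$ growth.

An identity worth knowing when testing: a series generated *exactly* by
the restored formula with continuous rate $a$ is refitted by the discrete
difference equation with $\hat a = 2\tanh(a/2)$, not $a$ itself (the two
agree to order $a^3/12$). Recovery assertions in the tests are written
against this identity; exact parameter recovery holds only for series
that satisfy the difference equation itself, e.g. geometric series, for
which $\hat a = -2(q-1)/(q+1)$ and $\hat b = 2c/(q+1)$ reproduce
$x(k) = c\,q^{k-1}$ with zero residuals.

## The strengthening buffer operator

Recorded data sometimes understate or overstate a trend because of
acquisition artefacts or external shocks. For a monotone series the grey
strengthening buffer operator

$$x(k)d = \frac{x(1) + \dots + x(k-1) + k\,x(k)}{2k - 1},
  \quad k = 1..n-1, \qquad x(n)d = x(n)$$

amplifies the trend: interior values are pulled toward the early level
(up for a decreasing series, down for an increasing one) while the most
recent observation is kept. At $k = 1$ the general formula reduces to
$x(1)$ through the empty prefix sum — it is implemented as the general
formula, not a special case — and constants are fixed points.

Two conventions matter in practice and are deliberate choices here:

* the operator computes at full floating precision, and a separate helper
  `round_display()` produces the conventional 2-decimal reporting values;
* when the buffered series feeds a *published-figure reproduction*, the
  2-decimal reported values are the modelling input (the published
  accumulations of the Three Gorges industrial series match the rounded
  column; fitting the unrounded transform shifts $a$ from 0.181 to
  0.182). The pipeline applies the operator at full precision by default;
  the reproduction paths round first.

The operator's meaning is only guaranteed for monotone input, but real
records may break monotonicity at a single point — the raw Three Gorges
industrial series itself turns upward in its final two years — so
non-monotone input warns rather than fails.

## Optimizing the initial condition

The classic choice $C = x^{(0)}(1)$ forces the fitted accumulated curve
through the first point, which nothing in the least-squares logic
justifies. `optimize_initial()` instead minimizes the sum of squared
relative simulation errors. Every restored value is affine in $C$, so
each relative residual is $r_k = p_k C + q_k$ and the objective
$\sum_k r_k^2$ is a strictly convex quadratic with closed-form minimizer
$C^* = -\sum p_k q_k / \sum p_k^2$. A golden-section search over the
exported objective serves as an independent oracle in the tests (they
agree to $10^{-6}$ across randomized fits).

The first-year term of the objective is genuinely ambiguous, because the
reported first fitted value is the observation itself while the restored
formula gives a different value at $k = 1$. Three conventions are
exposed via `objective_k1`:

* `ratio_to_first` (default): the $k=1$ residual is $(C - x(1))/x(1)$,
  i.e. the reported first value is $C$. This convention recovers the
  true $C$ on exactly generated series and best matches the published
  optimized values for the worked example;
* `restored_formula`: the $k=1$ residual uses
  $(1-e^{a})(C - b/a)$. Note that even at the true $C$ this residual is
  non-zero, so the variant shifts the optimum systematically;
* `exclude`: sum over $k = 2..n$ only.

No single convention reproduces all four published $C^*$ values of the
worked example exactly, so the reproduction pipeline checks them at a
tolerance of 0.15. This looseness is harmless: fitted and forecast
levels are insensitive to $C$ at that scale (a $\pm 0.1$ perturbation
moves every level by well under 0.02, a property the suite asserts), so
all table-level outputs are still checked at 2-decimal tightness.

## Adequacy diagnostics

Two tests grade a fit against the conventional I–IV thresholds
(`grade_table()`: average relative error 0.01/0.05/0.1/0.2, correlation
degree 0.9/0.8/0.7/0.6, both inclusive).

**Average relative error.** The restored simulation reports
$\hat x^{(0)}(1) = x^{(0)}(1)$ by convention, so its first relative error
is identically zero. The default therefore averages
$\Delta(k) = |\varepsilon(k)/x(k)|$ over $k = 2..n$ with divisor $n-1$;
including the structural zero (`divisor = "n"`) merely deflates the
statistic by $(n-1)/n$ and is provided for auditability. The $n-1$
convention is what reproduces the published adequacy table of the worked
example.

**Grey absolute correlation degree.** With
$|s| = |\sum_{k=2}^{n-1}(x(k) - x(1)) + \tfrac12 (x(n) - x(1))|$ for the
observed series, $|\hat s|$ for the fitted series and $|\hat s - s|$ for
their paired deviations,
$\eta = (1 + |s| + |\hat s|)/(1 + |s| + |\hat s| + |\hat s - s|) \in
(0, 1]$, with $\eta = 1$ exactly when the two swept-area statistics
coincide. The zero-first-error convention above is also what the
$s$-statistics assume.

## Numerical choices and degenerate inputs

* **$a \to 0$**: when $|a| < 10^{-12}$ all formulas switch to their
  analytic limits — restored values constant at $b$, time response
  $C + b(k-1)$ — avoiding division by $a$; `b_over_a` is reported as
  `NA`.
* **Applicability bound**: fits with $|a| \ge 2$ warn, since the
  restored model's one-step ratio $e^{-a}$ then distorts sign behaviour.
  For non-negative input the least-squares $a$ actually satisfies
  $|a| < 2$ strictly (it approaches 2 only for extreme decay), so the
  guard is a safety net for programmatic misuse rather than a reachable
  data condition.
* **Singular designs**: a constant mean sequence (possible only when all
  increments after the first observation vanish) aborts the fit.
* **Precision**: every downstream quantity (simulation, diagnostics,
  forecasts) uses full-precision $a$, $b$, $C$; rounding exists only at
  the reporting layer. Reproducing published tables at 2 decimals
  *requires* this — re-deriving them from 3-decimal printed parameters
  drifts visibly by the end of the forecast horizon.

## The synthetic generator and what passing tests show

`gm11_generate()` instantiates the restored-model equation as the
data-generating process and, for `noise_sd > 0`, multiplies each value
by an independent $1 + N(0, \sigma)$ factor. Multiplicative (relative)
noise is the natural companion of a relative-error objective and keeps
the diagnostics' scale invariance meaningful; draws that would produce a
non-positive value are rejected and resampled, and generation is
deterministic under a fixed seed.

The generator emulates only the statistical shape GM(1,1) assumes — a
quasi-exponential level with independent relative perturbations. It does
not emulate autocorrelated measurement error, structural breaks, or the
socioeconomic drivers of real emission series. Parameter-recovery
results (median $|\hat a - a|$ below 0.02 at 1% noise with $n = 7$, over
200 seeded replicates per setting — sizes chosen to make the Monte Carlo
checks sharp while keeping the whole suite interactive) therefore
certify the estimator's arithmetic and stability, not the model's
adequacy for any particular real series; the adequacy tests exist for
that judgement, one series at a time.

## Worked-example conditions

The packaged case study uses the four Three Gorges series at $n = 7$
(2008–2014), the strengthening buffer on the industrial record only
(stored at 2-decimal reporting precision), optimized initial values with
the default `ratio_to_first` convention, the $n-1$ error divisor, and a
6-year forecast horizon (2015–2020). `reproduce_three_gorges()` recomputes
all 79 published figures under these conditions and reports each against
its documented tolerance.

## Known limitations

* GM(1,1) assumes a single quasi-exponential regime; series with turning
  points need buffering, segmentation, or a different model class
  (GM(1,N), grey Verhulst and discrete DGM variants, and rolling
  refitting are out of scope here).
* Relative-error machinery requires strictly positive observations;
  zeros validate with a warning but break the objective and diagnostics.
* With $n$ this small, adequacy statistics are descriptive, not
  inferential — no sampling distribution is attached to $\bar\Delta$ or
  $\eta$.
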