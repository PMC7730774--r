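---
title: "Limits of agreement with the mean: model, inference, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Limits of agreement with the mean: model, inference, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loamci)
```

## The problem

When several observers (radiologists, raters, devices) measure the same
continuous quantity on the same subjects, the clinically relevant question is
often not whether two particular observers agree, but how far *any one
measurement* may stray from the consensus. Limits of agreement with the mean
(LOAM) answer this on the measurement scale itself: they are the symmetric
limits within which 95% of differences between an individual measurement and
the subject-specific mean are expected to fall. `loamci` estimates these
limits, attaches confidence intervals to them, quantifies the separate sources
of variation, and supports planning how many observers a future agreement
study needs.

## Model

Measurements follow the additive two-way random effects model

$$Y_{ijk} = \mu + A_i + B_j + E_{ijk},
\qquad i = 1,\dots,a,\; j = 1,\dots,b,\; k = 1,\dots,c,$$

with independent Gaussian subject effects $A_i \sim N(0, \sigma_A^2)$,
observer effects $B_j \sim N(0, \sigma_B^2)$ and residuals
$E_{ijk} \sim N(0, \sigma_E^2)$. The design must be balanced: every observer
measures every subject exactly $c$ times, with the $c$ repeats exchangeable.
Observers are modelled as a random sample from a population of observers —
the usual framing when the study's conclusions should generalise beyond the
raters at hand.

Under this model the difference between a measurement and its subject mean,
$D_{ijk} = Y_{ijk} - \bar Y_{i\cdot\cdot}$, is Gaussian with variance
$\frac{b-1}{b}\sigma_B^2 + \frac{bc-1}{bc}\sigma_E^2$, so the population
95% LOAM are

$$\pm\, 1.96 \sqrt{\tfrac{b-1}{b}\sigma_B^2 + \tfrac{bc-1}{bc}\sigma_E^2}.$$

Crucially this includes the inter-observer variance $\sigma_B^2$; the older
construction (`jones_loam()`), $\pm 1.96\,\hat\sigma_E$, uses only the
residual SD after removing observer effects and understates the spread
whenever observers differ systematically.

## Estimation

Everything is closed-form ANOVA. With subject, observer and residual sums of
squares $SSA$, $SSB$, $SSE$ (degrees of freedom $a-1$, $b-1$, $abc-a-b+1$),
the moment estimators are

$$\hat\sigma_A^2 = \frac{MSA - MSE}{bc},\quad
  \hat\sigma_B^2 = \frac{MSB - MSE}{ac},\quad
  \hat\sigma_E^2 = MSE,$$

and the LOAM estimate collapses to

$$\pm\,1.96\sqrt{(SSB + SSE)/N}, \qquad N = abc.$$

All replicated-design formulas reduce exactly to the single-measurement ones
at $c = 1$; the test suite asserts this, together with the decomposition
$SSA + SSB + SSE = \sum (y - \bar y)^2$ and the identity
$SSB + SSE = \sum (y_{ijk} - \bar y_{i\cdot\cdot})^2$, on randomly generated
balanced datasets.

$\hat\sigma_A^2$ and $\hat\sigma_B^2$ are unbiased but can be negative, by
sampling variation or because measurements by the same observer are genuinely
negatively correlated (a model violation). The package *never truncates them
to zero* — truncation would bias downstream quantities — it returns them
signed with a flag, and the report urges the analyst to judge whether the
model is misspecified or more observers are needed. The one exception is
`simulate.loam()`, where a Gaussian generator cannot take a negative
variance: there the component is clamped with a warning.

## Confidence intervals

* **LOAM** (`loam_ci()`): a Graybill–Wang interval for the linear variance
  combination $(SSB+SSE)/N$ inside the square root, transformed by square
  root and the 1.96 multiplier:
  $\bigl(1.96\sqrt{(SSB+SSE-L)/N},\, 1.96\sqrt{(SSB+SSE+H)/N}\bigr)$ with
  $L = \sqrt{l_B^2 SSB^2 + l_E^2 SSE^2}$,
  $H = \sqrt{h_B^2 SSB^2 + h_E^2 SSE^2}$,
  $l_x = 1 - 1/F_{0.975;\nu_x,\infty}$, $h_x = 1/F_{0.025;\nu_x,\infty} - 1$.
  Because $0 < l_x < 1$, the lower radicand is provably nonnegative. The CI
  for the lower limit is the negation of the endpoints. The interval is
  approximate; `coverage_study(target = "loam")` reproduces its calibration
  (about 95% already at $b = 10$, improving with $b$).
* **$\sigma_E$** (`sigma_E_ci()`): exact, from the pivot
  $SSE/\sigma_E^2 \sim \chi^2_{\nu_E}$. Its empirical coverage is
  statistically indistinguishable from nominal in the suite's
  10,000-replicate study.
* **$\sigma_B$, $\sigma_A$** (`sigma_B_ci()`, `sigma_A_ci()`): symmetric
  delta-method intervals, e.g.
  $\hat\sigma_B \pm \frac{1.96}{ac\,\hat\sigma_B}
  \sqrt{(ac\,\hat\sigma_B^2+\hat\sigma_E^2)^2/(2\nu_B)
  + (\hat\sigma_E^2)^2/(2\nu_E)}$.
  A negative lower bound is reported as computed (the interval is symmetric
  by construction); when the variance estimate itself is nonpositive, the
  delta method divides by zero or an imaginary SD, so the interval is flagged
  `undefined` rather than invented.
* **ICC(A,1)** (`icc_ci()`): the intraclass correlation for absolute
  agreement, $\sigma_A^2/(\sigma_A^2+\sigma_B^2+\sigma_E^2)$, is the unitless
  companion to the LOAM. Its CI follows McGraw & Wong's F-based construction
  with a Satterthwaite denominator df. The published formulas cover one
  measurement per cell; for $c > 1$ we re-derived the same construction from
  the replicated design's expected mean squares
  ($E[MSA] = bc\,\sigma_A^2 + \sigma_E^2$, $E[MSB] = ac\,\sigma_B^2 +
  \sigma_E^2$), which reduces verbatim to the published bounds at $c = 1$ —
  the suite checks this equality against an independent transcription of the
  single-measurement formulas.

Two levels are deliberately distinct: `loam_level` sets the inner coverage of
the limits (the 1.96), `level` the confidence of the intervals around them.
At 95% the multiplier is the literal 1.96 used throughout the printed
literature rather than `qnorm(0.975)` (they differ in the sixth significant
digit); other levels use exact quantiles. F-quantiles with infinite
denominator df are evaluated through the identity
$F_{\alpha;\nu,\infty} = \chi^2_{\alpha;\nu}/\nu$, avoiding reliance on a
library's handling of `Inf`.

## Planning the number of observers

The CI width is governed by $L$ and $H$, which shrink only as $b$ grows —
adding subjects alone does not deliver precision for the LOAM. Given pilot
values $\hat\sigma_{B,0}^2$, $\hat\sigma_{E,0}^2$ and a fixed $a$ (and $c$),
`expected_ci_width()` evaluates the width with the sums of squares replaced by
$SSB_0 = \nu_B(ac\,\hat\sigma_{B,0}^2 + \hat\sigma_{E,0}^2)$ and
$SSE_0 = \nu_E\,\hat\sigma_{E,0}^2$; the substitution is exact (asserted to
1e-9 in the tests). `required_observers()` returns the smallest integer
$b$ whose width does not exceed the target $W$ — the actionable design answer,
found by a linear scan over $b$ (widths are cheap to evaluate, and a scan is
robust to any non-monotonicity at tiny $b$; in practice the width is strictly
decreasing over $b \in [2, 200]$, which the suite asserts). The width is
interpreted as the full two-sided width of the CI for the upper LOAM.

```{r}
required_observers(sigma2_B0 = 0.09, sigma2_E0 = 0.36, a = 40, W = 0.35)
```

## The simulator and what passing tests show

`simulate_loam_data()` draws exactly from the model above: independent
Gaussian subject and observer effects plus i.i.d. Gaussian noise, balanced
design, homoscedastic throughout. Defaults in the validation studies mirror
the package's own calibration experiment: $a = 40$, $b = 10$, $c = 1$,
$\sigma_A = 1.5$, $\sigma_B = 0.3$, $\sigma_E = 0.6$ — a realistic clinical
imaging regime where subject variation dominates and observer variation is
half the residual scale. `coverage_study()` wraps the simulate–fit–cover loop
(2,000 replicates for the LOAM interval, 10,000 for the exact $\sigma_E$
interval in the shipped checks; a single root seed makes a study exactly
reproducible). Replicates whose requested interval is undefined (nonpositive
component estimate) are excluded from the coverage denominator and reported
as an exclusion rate, mirroring the reporting policy for negative estimates.

What this simulator does *not* emulate — heteroscedasticity, non-Gaussian
effects, subject-by-observer interaction, unbalanced or missing cells —
bounds what green tests mean: they validate the mathematics under the model,
not the model's fit to any particular dataset. For real data, start from the
agreement plot (`plot()` on the fit) and the per-observer summaries, and
export `residuals()` for standard diagnostics.

## Numerical and design choices

* Balance violations, duplicate replicate labels, and non-finite values are
  hard errors at construction; the estimators are never run on data they do
  not describe.
* `SSE` is computed from the residual definition and cross-checked against
  `total SS − SSA − SSB` inside `sums_of_squares()`; disagreement is an
  internal error, not a silent inaccuracy.
* Replicate labels never enter a formula (replicates are exchangeable by
  assumption); they are kept only for provenance and round-tripping.
* Rounding is presentation-only; all stored values are full precision.
* Degenerate inputs: all-equal measurements give zero sums of squares, zero
  limits and a degenerate `(0, 0)` interval; the ICC is an error there (zero
  total variance).
* The delimiter of input tables is auto-detected among comma/tab/semicolon;
  only `.` decimals are supported. Wide-format input is out of scope beyond
  ordinary reshaping by the user.

## Limitations

Unbalanced designs, fixed-observer-effect reformulations, interaction models,
marginal-model remedies for negative variance estimates, and
heteroscedastic/GLMM extensions are out of scope; the closed-form intervals
here are exactly what balance buys. The Graybill–Wang and delta-method
intervals are approximate — their accuracy improves with the number of
observers, and `coverage_study()` is the tool for judging them at your own
design's dimensions before trusting them at small $b$.

## Worked example

```{r, fig.width = 7, fig.height = 5}
f <- system.file("extdata", "synthetic_aorta_oto.csv", package = "loamci")
d <- read_agreement_table(f, columns = c(subject = "image",
                                         observer = "radiologist",
                                         value = "diameter",
                                         replicate = "take"),
                          unit = "mm")
fit <- loam(d)
summary(fit)
plot(fit)
```

The shipped file is *synthetic* — generated from the model at plausible
aortic-diameter parameters ($\mu = 21$ mm, $\sigma_A = 7.2$, $\sigma_B = 1.1$,
$\sigma_E = 1.2$ mm, $a = 50$, $b = 12$, $c = 2$) — and exists so the examples
and the end-to-end report have a realistic input; it is not the original
study data.
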