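---
title: "Biometrics and seasonal condition of Atlantic bluefin tuna: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biometrics and seasonal condition of Atlantic bluefin tuna: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bftbiom)
```

## The problem

Atlantic bluefin tuna (*Thunnus thynnus*) are measured and weighed under
dockside conditions that rarely permit the same measurement twice: some
fleets record straight fork length (SFL), others curved fork length (CFL)
or fin-to-snout proxies; weights may be round (RWT), gutted (GWT), gutted
and gilled (GGWT), or dressed (DWT). Stock assessment, however, needs one
weight-length relationship (WLR) per management unit — Eastern
(Atlantic + Mediterranean) and Western, split at 45°W. This package
implements the full analysis chain that turns such heterogeneous fishery
records into stock-specific annual and monthly WLRs:

1. **standardize** — robust linear conversions between measurement types,
   applied under a strict quality gate, yielding SFL_std (cm) and RWT_std (kg);
2. **wlr** — the allometric power law $W = \alpha L^\beta$ fitted by
   Gauss-Newton nonlinear least squares, weighted by the inverse CV of
   weight at length in 5 cm bins, with quantile-regression and bootstrap
   sensitivity analyses;
3. **popsim** — an age-structured simulator of the size distribution a
   sampling programme should see, used to judge representativeness;
4. **condition** — scaled residuals from the annual fit modelled on month,
   maturity and area, giving monthly exponents via least-squares means;
5. **synthetic data** — a generator producing fishery-like datasets with
   known truth, so every stage above is testable without confidential
   landings data.

## Measurement standardization

Length-length and weight-weight conversions are straight lines
$y = \alpha + \beta x$ fitted by iteratively reweighted least squares with
the Tukey bisquare weight (tuning constant 4.685, OLS start, MAD residual
scale, convergence when the largest relative coefficient change drops
below $10^{-8}$). The bisquare choice is a package decision: the estimator
family is "robust linear fitting" and bisquare is the common default; a
Huber variant would differ only in how hard gross outliers are rejected.
Reported $r^2$ is the squared Pearson correlation of observed and fitted
values.

A conversion may be used for standardization only when $r^2 \ge 0.98$
(the gate is a tunable argument). In practice this admits CFL→SFL plus
GWT→RWT and GGWT→RWT in the East and CFL→SFL plus DWT→RWT in the West;
head, preopercular and first-dorsal lengths never pass and are fitted for
reporting only. Measured values are never altered; a conversion failing
the gate is refused aloud, never silently applied. Where both GWT and GGWT
are available the GWT conversion is preferred: gutting alone is the
smaller intervention, so its conversion to round weight carries less
model error. Standardization removes no outliers (the robust fit already
downweights them); an optional 5-residual-SE screen for gross recording
errors exists but is off by default.

## The weighted power-law fit

Weight variance grows with length, and for allometric exponents near 3
the usual regression assumptions degrade precisely where the fish are
biggest. The observed CV of weight at length is therefore summarized in
half-open 5 cm bins ($[L, L+5)$, anchored at 0), with sparse bins
(fewer than 10 fish) flagged and imputed with the stock-wide mean CV. The
annual fit minimizes

$$\sum_i w_i \left(W_i - \alpha L_i^{\beta}\right)^2,\qquad
w_i = 1/\mathrm{CV}(\mathrm{bin}(L_i)),$$

by Gauss-Newton iteration from the log-log OLS start, with step halving
and convergence at a relative SSE change below $10^{-10}$. The weight is
$1/\mathrm{CV}$, exactly the stated weighting factor, not the
variance-motivated $1/\mathrm{CV}^2$; a `cv_power = 2` toggle provides
the latter. AIC is computed under a Gaussian likelihood on unweighted
residuals, and non-convergence is flagged rather than silently reported.

Two sensitivity analyses accompany the fit. Nonlinear **quantile
regression** minimizes the pinball loss for the same power-law family;
because the loss is non-smooth the search is Nelder-Mead over
$(\log\alpha, \beta)$ from the least-squares solution, restarted once,
with tolerance $10^{-8}$. Quantile curves are unweighted by default (the
CV weights exist to stabilize the mean fit; the quantile objective is
already robust). Two **bootstrap** schemes (1000 replicates in the
headline configuration) refit the whole procedure per replicate,
including the bin-CV profile: equal-probability resampling of n from n,
and a what-if design drawing a constant number (default 100) from every
non-empty 5 cm bin between 30 and 300 cm.

## Sampling representativeness

The expected size composition of an unfished bluefin-like population is a
survivorship-weighted mixture of normal size-at-age distributions:
$N_1 = 1$, $N_{a+1} = N_a e^{-(M_a+F_a)}$, a terminal plus-group closed by
the geometric sum $N_A e^{-Z_A}/(1-e^{-Z_A})$, and
$\sigma_a = 0.125\,\mu_a$ (a 12.5% CV of length at age). Per-1 cm bin
proportions are normal bin integrals; a knife-edge minimum size (75 cm
SFL East, 170 cm West) zeroes the small bins before renormalization.
Observed and expected compositions are compared by the maximum CDF
difference (the Kolmogorov-Smirnov distance). Fishing mortality defaults
to zero — the representativeness question is about what an unfished
population would offer a non-selective sampler — but an F-at-age vector is
accepted.

The mortality and growth defaults (East M-at-age declining from 0.49 at
age 1 to 0.10 at ages 10+, von Bertalanffy $L_\infty = 318.85$,
$k = 0.093$, $t_0 = -0.97$; West flat M = 0.14, $L_\infty = 314.9$,
$k = 0.089$, $t_0 = -1.13$) are the values long used in ICCAT assessment
practice. They are **user-replaceable defaults**, supplied because the
analysis needs *a* plausible age structure; nothing downstream is
calibrated to them, and the published small-fish proportions cannot be
reproduced exactly without the assessment input files, which is why the
package treats those proportions as illustrative rather than as checks.
Ages are whole years with no within-year growth; the season enters through
the condition model, not through size-at-age.

## Seasonal condition

Condition is measured by scaled residuals $(W_\mathrm{obs} -
W_\mathrm{pred})/W_\mathrm{pred}$ from the annual weighted fit — raw
residuals grow with size, scaled ones do not. Residuals above 1 (observed
weight more than double the prediction) are excluded in one pass, with
exactly 1 retained; the lower bound is $-1$ by construction, so only the
upper tail is ever trimmed. Each residual carries month, maturity
(mature at $\ge$ 130 cm SFL in the East, $\ge$ 185 cm in the West) and an
area group (East: east Atlantic, west-central Mediterranean including the
Strait of Gibraltar, eastern Mediterranean; the West is one group — Gulf
of Mexico observations are too few to stand alone as a factor).

The condition model is an ordinary least-squares fit of the retained
residuals on SFL_std (continuous) and the chosen factors, with sum-to-zero
contrasts so factor effects are departures from the overall mean.
Per-factor explained deviance is the Type III (marginal) sum of squares;
year can be included for that diagnostic but stays out of the final
monthly model. Monthly **least-squares means** are balanced-grid
predictions — every combination of the other factor levels counted once,
SFL fixed at its mean — so unequal monthly sampling across areas and
maturity states does not contaminate the seasonal signal; they are
centered to zero across months. The monthly coefficient table then
perturbs the annual exponent:

$$\beta_m = \beta + \mathrm{LSMean}_m \times \mathrm{MSE},$$

with $\alpha$ unchanged. Whether the scaling constant should be the
residual mean square or its square root is ambiguous in the source
material; the package implements the mean square as written and exposes
`use_sqrt_mse = TRUE`. On synthetic data the package's own runs show the
$\sqrt{\mathrm{MSE}}$ variant producing monthly exponent ranges of the
same order as the published tables while the MSE variant compresses them
roughly tenfold — suggestive, but not decidable without the original
data, so the written form stays the default.

## The synthetic-data generator

The generator is first-class, tested code. It emulates the features the
analysis is sensitive to:

* ages drawn in proportion to survivorship; lengths normal around mean
  length-at-age with a 12.5% CV, truncated positive;
* weights from the true allometry with **multiplicative lognormal noise**,
  $\sigma(L) = \sqrt{\log(1+\mathrm{CV}(L)^2)}$, so weights stay positive
  and the realized CV of weight at length matches a configured profile.
  The default profiles are piecewise-linear traces of the observed
  patterns: East starting near 20% for small fish, falling to 9% at
  mid-sizes, rising to 12.5% for the largest; West near 13% for small
  fish with a pronounced 35% bulge at 160-200 cm;
* a 12-month cycle of exponent offsets (centered to zero; defaults are
  the centered deviations of the published monthly exponents), injected
  as $\beta + \delta_{m}$ so seasonal condition is recoverable truth;
* fleets with distinct gears, areas, active months, knife-edge minimum
  sizes (75/170 cm), optional selectivity curves, measurement-type
  subsets and per-type additive noise truncated at zero. A small
  "research" fleet measures several types on the same fish and is exempt
  from the minimum size — without dual-measured fish no conversion could
  be fitted, mirroring the laboratory fraction of real sampling
  programmes;
* one global seed: every stochastic stage draws from a single stream in
  fixed order, so identical configurations are byte-identical.

What the generator does **not** emulate: real spatial structure and
migration (areas are labels, not habitats), within-year growth,
non-power-law curvature of the true weight-length relation, and
recording errors beyond additive noise. Tests passing on synthetic data
therefore demonstrate that the estimators recover known structure of the
assumed form — not that real bluefin data satisfy those assumptions.

## Numerical choices and degenerate inputs

* Gauss-Newton and the robust IRLS both guard degenerate cases: exact
  fits (zero MAD) terminate immediately; non-positive measurements are
  rejected; empty generations return empty, schema-correct frames.
* Bin membership is half-open $[L, L+5)$ anchored at 0 cm; the edge
  convention is a package decision.
* The quantile objective's Nelder-Mead is restarted once from its own
  optimum; unit tests verify it is never beaten by an exact LP solution
  of the log-scale problem on its own loss.
* The condition model refuses aliased designs with an error naming the
  empty factor cells; additive models tolerate empty month-by-area cells
  without aliasing, so the check triggers only on true confounding.
* Plus-group closure requires a positive terminal Z; a zero-mortality
  toy model is valid only without a plus-group.

## Design choices on open points

* **Bootstrap scheme comparison.** With original-scale least squares,
  large fish dominate the criterion at any sample composition, so
  resampling schemes differ materially only when the largest sizes leave
  the resampled range. The package's paired comparison therefore uses
  data whose top sizes exceed the 300 cm resampling cap and follow a
  heavier local weight regime — both features documented for real
  Western samples (lengths beyond 300 cm; anomalous weight variability
  near 300 cm). Under those conditions the uniform-per-bin fit reliably
  fails the largest decile, reproducing the qualitative finding the
  scheme comparison exists to demonstrate.
* **Stock separation.** Conversions and WLRs are always fitted within a
  stock; pooling across the 45°W line is never done.
* **Overall percent difference between stocks.** The averaging grid and
  denominator are exposed as arguments (default: 60-280 cm in 10 cm
  steps, denominator the second fit) rather than fixed, since neither is
  canonical.
* **Problem sizes.** The bundled analysis scripts use 20,000-record
  synthetic samples, bootstrap summaries at B = 200 and headline
  configurations at B = 1000; parameter-recovery checks use 20 seeds at
  n = 20,000 and the precision check n = 50,000, B = 200. These sizes
  give Monte-Carlo error comfortably below the tolerances being checked.

## Known limitations

* The Western CV profile's 35% mid-size bulge makes original-scale least
  squares noticeably attenuate the exponent on synthetic Western data
  (the median quantile fit, which is immune to the lognormal mean
  inflation, recovers it); parameter-recovery guarantees are therefore
  stated for the Eastern-style configuration.
* Published conversions are fitted to real scatter; the generator's
  truth conversions are the printed lines, so synthetic refits reproduce
  the printed coefficients only up to the generator's noise model.
* LD1/HeadL/PreopL chains, farm weight-gain estimation, spatial mapping
  and assessment use of the WLRs are out of scope.
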