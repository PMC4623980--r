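# bftbiom

Biometric relationships and seasonal condition of Atlantic bluefin tuna
(*Thunnus thynnus*), as an installable, tested R analysis package.

## The problem

Bluefin tuna landings are measured in whatever way the dockside allows:
straight or curved fork length (SFL, CFL), first-dorsal/head/preopercular
lengths, and round, gutted, gutted-and-gilled, or dressed weights (RWT,
GWT, GGWT, DWT). Assessment and management need one weight-length
relationship per stock (Eastern Atlantic + Mediterranean, Western
Atlantic) in common units. This package implements the whole chain:

* **Standardization** — robust linear conversions between measurement
  types (IRLS with Tukey bisquare), applied only when their coefficient
  of determination passes a quality gate (r² ≥ 0.98), producing SFL_std
  (cm) and RWT_std (kg).
* **Weight-length fitting** — the allometric power law
  `RWT = alpha * SFL^beta` by Gauss-Newton nonlinear least squares,
  weighted by the inverse CV of weight at length in 5 cm bins, so that
  sizes with anomalously variable weights do not dominate.
* **Sensitivity analyses** — nonlinear quantile regression (pinball loss)
  across the 2.5-97.5% band, and two bootstrap schemes: ordinary
  equal-probability resampling and a what-if design with a constant
  number of fish per 5 cm bin.
* **Sampling representativeness** — an age-structured simulator
  (survivorship × normal size-at-age, CV 12.5%, optional knife-edge
  selectivity at 75/170 cm SFL) producing the expected per-1 cm sampling
  proportions, compared to samples by KS distance.
* **Seasonal condition** — scaled residuals `(obs − pred)/pred` from the
  annual fit, modelled on month, maturity and area with effects coding;
  monthly least-squares means feed the monthly coefficient table
  `beta_m = beta + LSMean_m × MSE`.
* **Synthetic fishery generator** — produces datasets with known truth
  (mixed measurement types per fleet, minimum-size truncation,
  size-dependent weight CV, injected seasonal cycle) so every stage is
  testable without confidential landings data.

The published coefficient tables for both stocks ship as fixtures
(`bft_coefficients()`, `bft_annual_wlr()`, `bft_monthly_wlr()`), so all
deterministic quantities derivable from them are reproducible without any
raw data.

## Worked example

Published-curve arithmetic needs no data:

```r
library(bftbiom)
east <- bft_annual_wlr("EAST")   # RWT = 3.51e-05 * SFL^2.8785
west <- bft_annual_wlr("WEST")   # RWT = 1.77e-05 * SFL^3.0013

predict_weight(east, 100)
#> [1] 20.0589      # kg: a 100 cm Eastern fish

compare_wlrs(east, west, grid = c(110, 170, 250), denominator = "B")$table
#>   sfl    w_a    w_b pct_diff
#> 1 110  26.39  23.70    11.34   # East fish are ~11% heavier at 110 cm
#> 2 170  92.40  87.54     5.54   # ~6% at 170 cm
#> 3 250 280.40 278.55     0.66   # curves nearly cross for the largest fish

predict_monthly_weight(bft_monthly_wlr("EAST"), 200, month = 5)
#> [1] 154.1489    # May (post-feeding peak) vs 147.5 kg annual
```

The full pipeline on a synthetic Eastern sample:

```r
rec  <- simulate_fishery(generator_config("EAST", seed = 1),
                         target_records = 10000)
conv <- fit_stock_conversions(rec, "EAST")
conv[["CFL->SFL"]]
#> SFL = 1.8433 + 0.9515 x CFL  (ROBUST, n = 2968, r2 = 1.000, RSE = 0.560)

std <- standardize_records(rec, conv)       # r2 >= 0.98 gate
fit <- fit_power_law(wlr_input(std)$sfl_std, wlr_input(std)$rwt_std,
                     weighting = "INV_CV")
fit
#> W = 3.06e-05 x L^2.9047  (weighting INV_CV, n = 10000, RMSE = 24.115, converged: TRUE)
```

`run_pipeline(pipeline_config(stock = "EAST", seed = 1))` chains every
stage (conversions, gate, bin CVs, weighted/unweighted fits, quantile
fits, both bootstraps, representativeness, condition model, monthly
table) and returns a deterministic JSON-able report.

## The analysis

The numbered drivers under `analysis/` rerun the study workflow on
synthetic data and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # two 20,000-record stock datasets
Rscript analysis/02_standardize.R   # conversions vs published tables
Rscript analysis/03_fit_wlr.R       # annual fits, stock comparison, fixed factors
Rscript analysis/04_sensitivity.R   # quantile curves, bootstrap schemes
Rscript analysis/05_popsim.R        # expected size distributions, KS distances
Rscript analysis/06_condition.R     # monthly LSMeans and coefficient table
```

## Scope

Fitting chains through LD1/HeadL/PreopL (their conversions are reported
but fail the gate), farm weight-gain estimation, spatial analysis and
stock-assessment use of the relationships are out of scope. See
`vignettes/bluefin-biometrics.Rmd` for the methods account, parameter
meanings, numerical choices and limitations.
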