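test_that("bin statistics match hand computation", {
  std <- data.frame(sfl_std = c(101, 102, 104), rwt_std = c(10, 12, 14))
  prof <- bin_cv_profile(std, min_count = 3)
  expect_equal(prof$bin_lower, 100)
  expect_equal(prof$mean_w, 12)
  expect_equal(prof$sd_w, 2)
  expect_equal(prof$cv, 2 / 12, tolerance = 1e-12)
  # constant bin: zero CV
  const <- bin_cv_profile(data.frame(sfl_std = c(101, 102, 103),
                                     rwt_std = c(12, 12, 12)), min_count = 3)
  expect_equal(const$cv, 0)
  # empty input: empty profile
  empty <- bin_cv_profile(data.frame(sfl_std = numeric(), rwt_std = numeric()))
  expect_equal(nrow(empty), 0)
})

test_that("sparse bins are flagged and imputed with the stock-wide mean CV", {
  set.seed(2)
  std <- data.frame(sfl_std = c(runif(200, 100, 110), 201),
                    rwt_std = c(rlnorm(200, 3, 0.1), 90))
  prof <- bin_cv_profile(std, min_count = 10)
  sparse <- prof[prof$bin_lower == 200, ]
  expect_true(sparse$imputed)
  expect_equal(sparse$cv, attr(prof, "mean_cv"))
  expect_false(any(prof$imputed[prof$n >= 10]))
})

test_that("noise-free power-law data is recovered to numerical precision", {
  l <- seq(40, 280, by = 2)
  w <- 2e-5 * l^3
  f <- fit_power_law(l, w)
  expect_equal(f$alpha, 2e-5, tolerance = 1e-6)
  expect_equal(f$beta, 3, tolerance = 1e-6)
  expect_true(f$converged)
})

test_that("the weighted optimum beats a +/-1% brute-force parameter grid", {
  d <- make_power_data(2000, cv = 0.15, seed = 3)
  prof <- bin_cv_profile(data.frame(sfl_std = d$sfl, rwt_std = d$rwt))
  f <- fit_power_law(d$sfl, d$rwt, weighting = "INV_CV", cv_profile = prof)
  w <- bftbiom:::cv_weights(d$sfl, prof)
  s_opt <- weighted_sse(f$alpha, f$beta, d$sfl, d$rwt, w)
  rel <- seq(-0.01, 0.01, length.out = 21)
  for (da in rel) for (db in rel) {
    if (da == 0 && db == 0) next
    expect_gte(weighted_sse(f$alpha * (1 + da), f$beta * (1 + db),
                            d$sfl, d$rwt, w), s_opt)
  }
})

test_that("weighted and unweighted fits coincide when all bin CVs are equal", {
  d <- make_power_data(1500, cv = 0.1, seed = 4)
  prof <- bin_cv_profile(data.frame(sfl_std = d$sfl, rwt_std = d$rwt))
  prof$cv <- 0.1  # force equal weights
  fw <- fit_power_law(d$sfl, d$rwt, weighting = "INV_CV", cv_profile = prof)
  fu <- fit_power_law(d$sfl, d$rwt, weighting = "NONE")
  expect_equal(fw$alpha, fu$alpha, tolerance = 1e-8)
  expect_equal(fw$beta, fu$beta, tolerance = 1e-8)
})

test_that("Gauss-Newton agrees with an independent Levenberg-Marquardt fit", {
  d <- make_power_data(3000, cv = 0.12, seed = 5)
  prof <- bin_cv_profile(data.frame(sfl_std = d$sfl, rwt_std = d$rwt))
  w <- bftbiom:::cv_weights(d$sfl, prof)
  ours <- fit_power_law(d$sfl, d$rwt, weighting = "INV_CV", cv_profile = prof)
  ref <- minpack.lm::nlsLM(rwt ~ a * sfl^b, data = d, weights = w,
                           start = list(a = 1e-5, b = 3),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  expect_equal(ours$alpha, unname(coef(ref)["a"]), tolerance = 1e-5)
  expect_equal(ours$beta, unname(coef(ref)["b"]), tolerance = 1e-6)
})

test_that("parameter recovery on heteroscedastic generator data", {
  cfg <- generator_config("EAST", n_fish = 20000, seed = 6, true_beta = 2.9)
  pop <- generate_population(cfg)
  for (wt in c("INV_CV", "NONE")) {
    f <- fit_power_law(pop$sfl, pop$rwt, weighting = wt)
    expect_lt(abs(f$beta - 2.9), 0.03)
  }
})

test_that("predicted weights reproduce the published values", {
  east <- bft_annual_wlr("EAST")
  west <- bft_annual_wlr("WEST")
  expect_equal(predict_weight(east, 100), 3.51e-5 * 100^2.8785, tolerance = 1e-12)
  expect_equal(predict_weight(east, 100), 20.06, tolerance = 0.01)
  expect_equal(predict_weight(west, 200), 1.77e-5 * 200^3.0013, tolerance = 1e-12)
  expect_equal(predict_weight(west, 200), 142.7, tolerance = 0.005 * 142.7)
  expect_equal(predict_weight(east, 1), east$alpha)
  expect_error(predict_weight(east, -5), "positive")
})

test_that("quantile fits collapse to the LS fit on noise-free data", {
  l <- seq(50, 250, by = 1)
  w <- 3e-5 * l^2.9
  for (tau in c(0.25, 0.5, 0.75)) {
    q <- fit_power_quantile(l, w, tau = tau)
    expect_equal(q$alpha, 3e-5, tolerance = 1e-4)
    expect_equal(q$beta, 2.9, tolerance = 1e-5)
  }
})

test_that("exchange quantile solver equals exhaustive pair enumeration", {
  d <- make_power_data(200, cv = 0.1, seed = 7)
  for (tau in c(0.25, 0.5, 0.75)) {
    ex <- exchange_quantile_loglinear(d$sfl, d$rwt, tau)
    bf <- brute_quantile_loglinear(d$sfl, d$rwt, tau)
    expect_equal(ex$loss, bf$loss, tolerance = 1e-10)
    expect_equal(ex$beta, bf$beta, tolerance = 1e-10)
  }
})

test_that("pinball fit matches the back-transformed log-linear quantile fit", {
  # quantiles are equivariant under monotone transforms, so both fits
  # target the same curve; agreement is checked where finite-sample
  # criterion noise sits below the tolerance
  d <- make_power_data(8000, cv = 0.005, l_range = c(30, 300), seed = 7)
  for (tau in c(0.5, 0.75)) {
    q <- fit_power_quantile(d$sfl, d$rwt, tau = tau)
    oracle <- exchange_quantile_loglinear(d$sfl, d$rwt, tau)
    expect_lt(abs(q$alpha - oracle$alpha) / oracle$alpha, 0.005)
    expect_lt(abs(q$beta - oracle$beta) / oracle$beta, 0.005)
    # and the nonlinear fit truly minimizes its own criterion: it must not
    # lose to the oracle's parameters on the original-scale pinball loss
    pin <- function(a, b) {
      r <- d$rwt - a * d$sfl^b
      sum(r * (tau - (r < 0)))
    }
    expect_lte(pin(q$alpha, q$beta), pin(oracle$alpha, oracle$beta))
  }
})

test_that("quantile curves are monotone in tau and median sits below the mean", {
  d <- make_power_data(4000, cv = 0.15, seed = 8)
  ls <- fit_power_law(d$sfl, d$rwt)
  taus <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  fits <- lapply(taus, function(t) fit_power_quantile(d$sfl, d$rwt, tau = t,
                                                      start = ls))
  grid <- seq(60, 260, by = 20)
  pred <- sapply(fits, function(f) predict_weight(f, grid))
  expect_true(all(diff(t(pred)) >= -1e-8))  # non-decreasing in tau
  # lognormal noise: the median curve lies below the mean curve everywhere
  expect_true(all(predict_weight(fits[[3]], grid) < predict_weight(ls, grid)))
  expect_error(fit_power_quantile(d$sfl, d$rwt, tau = 1.2), "tau")
})

test_that("degenerate resampling returns the point estimate in every replicate", {
  l <- seq(60, 240, by = 1)
  w <- 2e-5 * l^3
  b <- bootstrap_wlr(l, w, scheme = "EQUAL_PROB", B = 10, seed = 1,
                     weighting = "NONE")
  expect_true(all(abs(b$replicates$beta - b$point$beta) < 1e-6))
  expect_true(all(abs(b$replicates$alpha - b$point$alpha) /
                    b$point$alpha < 1e-4))
})

test_that("equal-probability bootstrap is centered on the point estimate", {
  d <- make_power_data(5000, cv = 0.1, seed = 9)
  b <- bootstrap_wlr(d$sfl, d$rwt, scheme = "EQUAL_PROB", B = 200, seed = 10,
                     weighting = "INV_CV")
  mc_se <- sd(b$replicates$beta) / sqrt(b$B)
  expect_lt(abs(b$summary$beta[["mean"]] - b$point$beta), 2 * mc_se)
})

test_that("bootstrap is reproducible under its seed", {
  d <- make_power_data(800, cv = 0.1, seed = 11)
  b1 <- bootstrap_wlr(d$sfl, d$rwt, B = 20, seed = 5)
  b2 <- bootstrap_wlr(d$sfl, d$rwt, B = 20, seed = 5)
  expect_identical(b1$replicates, b2$replicates)
})

test_that("uniform-per-bin resampling degrades the fit for the largest fish", {
  # size-imbalanced sample (90% of fish below 100 cm) whose largest fish
  # lie beyond the 300 cm resampling cap and follow a heavier local
  # weight-length regime: only the equal-probability scheme keeps them as
  # anchors, so the uniform-bin fit fails the top size decile
  d <- make_regime_shift_data(n = 8000, seed = 1)
  eq <- bootstrap_wlr(d$sfl, d$rwt, scheme = "EQUAL_PROB", B = 60, seed = 101,
                      weighting = "NONE")
  un <- bootstrap_wlr(d$sfl, d$rwt, scheme = "UNIFORM_PER_BIN", B = 60,
                      seed = 101, weighting = "NONE", m_per_bin = 100)
  top <- which(d$sfl >= quantile(d$sfl, 0.9))
  expect_gt(bootstrap_curve_mar(un, d$sfl, d$rwt, top),
            bootstrap_curve_mar(eq, d$sfl, d$rwt, top))
})

test_that("curve comparison reproduces the published stock differences", {
  east <- bft_annual_wlr("EAST")
  west <- bft_annual_wlr("WEST")
  ident <- compare_wlrs(east, east, grid = c(80, 150, 250))
  expect_true(all(abs(ident$table$pct_diff) < 1e-12))
  cmp <- compare_wlrs(east, west, grid = c(110, 170), denominator = "B")
  expect_equal(cmp$table$pct_diff[1], 11.34, tolerance = 0.015)
  expect_equal(cmp$table$pct_diff[2], 5.54, tolerance = 0.015)
})

test_that("fixed-factor divergence matches the published conversion line", {
  ggwt <- bft_conversion("EAST", "GGWT", "RWT")
  expect_equal(compare_fixed_factor(ggwt, 1.13, 239), 15.07, tolerance = 0.01)
  expect_equal(compare_fixed_factor(ggwt, 1.16, 239), 12.82, tolerance = 0.01)
  # a factor equal to the slope of a through-origin line diverges nowhere
  line <- linear_conversion("GGWT", "RWT", 0, 1.2, 0.99, 1, 10,
                            c(1, 300), c(1, 360))
  expect_equal(compare_fixed_factor(line, 1.2, c(10, 100, 250)), rep(0, 3))
  expect_warning(compare_fixed_factor(ggwt, 1.13, 500), "range")
})
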