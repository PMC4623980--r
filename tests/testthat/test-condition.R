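std_frame <- function(sfl, rwt, month = 6, area = "WM", stock = "EAST") {
  n <- length(sfl)
  data.frame(fish_id = seq_len(n), stock = stock, area = area,
             gear = "LONGLINE", year = 2010, month = month,
             sfl_std = sfl, rwt_std = rwt,
             sfl_source = "MEASURED", rwt_source = "MEASURED",
             stringsAsFactors = FALSE)
}

test_that("scaled residuals implement the exclusion and maturity rules", {
  fit <- power_law_fit(alpha = 2e-5, beta = 3)
  pred130 <- 2e-5 * 130^3
  std <- std_frame(
    sfl = c(100, 100, 130, 129.9, 100, 100),
    rwt = c(2e-5 * 100^3,      # exact prediction
            45 * (2e-5 * 100^3) / 20,  # scaled residual 1.25
            pred130, pred130 * 0.5,
            2 * 2e-5 * 100^3,  # exactly double: residual exactly 1
            0.001))            # near-zero weight: residual near -1
  r <- scaled_residuals(std, fit)
  expect_equal(r$value[1], 0)
  expect_false(r$excluded[1])
  expect_equal(r$value[2], 1.25)
  expect_true(r$excluded[2])
  expect_equal(r$maturity[3], "MATURE")    # at the 130 cm threshold
  expect_equal(r$maturity[4], "IMMATURE")  # just below it
  expect_equal(r$value[5], 1)
  expect_false(r$excluded[5])              # exactly 1 is retained
  expect_true(all(r$value >= -1))          # weights are non-negative
  expect_true(all(!r$excluded | r$value > 1))  # only the upper tail goes
})

test_that("area grouping and the West maturity threshold are applied", {
  fit <- power_law_fit(alpha = 2e-5, beta = 3)
  std <- std_frame(sfl = c(185, 184), rwt = 2e-5 * c(185, 184)^3,
                   area = c("SG", "GSL"), stock = "WEST")
  r <- scaled_residuals(std, fit)
  expect_equal(r$maturity, c("MATURE", "IMMATURE"))
  expect_equal(r$area_group, c("WC_MED", "WEST_ATLANTIC"))
})

test_that("null data yields a null condition model", {
  set.seed(5)
  n <- 2400
  resid <- data.frame(
    fish_id = 1:n, sfl_std = runif(n, 80, 250),
    month = rep(1:12, each = n / 12), year = 2010,
    maturity = rep(c("IMMATURE", "MATURE"), n / 2),
    area_group = "WC_MED", value = rnorm(n, 0, 0.1), excluded = FALSE
  )
  m <- fit_condition_model(resid, factors = c("month", "maturity"))
  expect_lt(max(abs(lsmeans_month(m))), 3 * 0.1 / sqrt(n / 12))
  expect_equal(m$mse, 0.01, tolerance = 0.15)
})

test_that("injected monthly effects dominate and are recovered in order", {
  set.seed(6)
  n <- 12000
  month <- sample(1:12, n, replace = TRUE, prob = c(rep(1, 6), rep(3, 6)))
  eff <- seq(-0.05, 0.05, length.out = 12)  # +/- 5% condition cycle
  resid <- data.frame(
    fish_id = 1:n, sfl_std = runif(n, 80, 250), month = month, year = 2010,
    maturity = sample(c("IMMATURE", "MATURE"), n, TRUE),
    area_group = sample(c("WC_MED", "E_MED"), n, TRUE, prob = c(0.9, 0.1)),
    value = eff[month] + rnorm(n, 0, 0.04), excluded = FALSE
  )
  m <- fit_condition_model(resid)
  ls <- lsmeans_month(m)
  expect_equal(cor(ls, eff, method = "spearman"), 1)
  dev <- m$deviance
  ss <- dev[["Sum of Sq"]]
  names(ss) <- rownames(dev)
  expect_gt(ss[["month"]], ss[["maturity"]])
  expect_gt(ss[["month"]], ss[["area_group"]])
})

test_that("month-to-year deviance ratio reflects a 4x injected effect", {
  set.seed(7)
  n <- 4800
  month <- sample(1:12, n, TRUE)
  year <- sample(2005:2010, n, TRUE)
  m_eff <- 0.04 * sin(2 * pi * (1:12) / 12)
  y_eff <- 0.01 * scale(rnorm(6))[, 1]
  resid <- data.frame(
    fish_id = 1:n, sfl_std = runif(n, 80, 250), month = month, year = year,
    maturity = "MATURE", area_group = "WC_MED",
    value = m_eff[month] + y_eff[year - 2004] + rnorm(n, 0, 0.08),
    excluded = FALSE
  )
  m <- fit_condition_model(resid, factors = c("month", "year"))
  ss <- m$deviance[["Sum of Sq"]]
  names(ss) <- rownames(m$deviance)
  expect_gt(ss[["month"]] / ss[["year"]], 1)
})

test_that("type III sums of squares match car::Anova", {
  set.seed(8)
  n <- 1200
  resid <- data.frame(
    fish_id = 1:n, sfl_std = runif(n, 80, 250),
    month = sample(1:12, n, TRUE, prob = c(rep(1, 4), rep(4, 8))),
    year = 2010,
    maturity = sample(c("IMMATURE", "MATURE"), n, TRUE, prob = c(0.7, 0.3)),
    area_group = "WC_MED",
    value = rnorm(n, 0, 0.1), excluded = FALSE
  )
  m <- fit_condition_model(resid, factors = c("month", "maturity"))
  ref <- car::Anova(m$lm, type = 3)
  ss <- m$deviance[["Sum of Sq"]]
  names(ss) <- rownames(m$deviance)
  expect_equal(ss[["month"]], ref["month", "Sum Sq"], tolerance = 1e-8)
  expect_equal(ss[["maturity"]], ref["maturity", "Sum Sq"], tolerance = 1e-8)
})

test_that("balanced designs make LSMeans equal raw monthly means", {
  set.seed(9)
  grid <- expand.grid(month = 1:12, maturity = c("IMMATURE", "MATURE"),
                      rep = 1:40)
  grid$value <- rnorm(nrow(grid), 0, 0.05)
  resid <- data.frame(
    fish_id = seq_len(nrow(grid)), sfl_std = 150, month = grid$month,
    year = 2010, maturity = grid$maturity, area_group = "WC_MED",
    value = grid$value, excluded = FALSE
  )
  m <- fit_condition_model(resid, factors = c("month", "maturity"),
                           include_sfl = FALSE)
  raw <- tapply(resid$value, resid$month, mean)
  expect_equal(lsmeans_month(m), as.numeric(raw - mean(raw)),
               tolerance = 1e-10)
})

test_that("unbalanced 2x2 LSMeans equal hand-computed balanced-grid averages", {
  # additive cell means with zero noise: predictions equal the cell means,
  # so the balanced-grid month means are hand-enumerable
  cells <- expand.grid(month = 1:2, maturity = c("IMMATURE", "MATURE"))
  cells$mean <- c(0.01, -0.03, 0.03, -0.01)   # mu + a_m + b_mat, additive
  counts <- c(10, 3, 2, 15)                   # heavily unbalanced
  rows <- cells[rep(seq_len(4), counts), ]
  resid <- data.frame(
    fish_id = seq_len(nrow(rows)), sfl_std = 150, month = rows$month,
    year = 2010, maturity = rows$maturity, area_group = "WC_MED",
    value = rows$mean, excluded = FALSE
  )
  # perfect fit: lm warns that its F statistics are unreliable, which is
  # irrelevant here since only the predictions are used
  m <- suppressWarnings(fit_condition_model(resid,
                                            factors = c("month", "maturity"),
                                            include_sfl = FALSE))
  ls <- lsmeans_month(m)
  # hand: month 1 -> (0.01 + 0.03)/2 = 0.02; month 2 -> -0.02; centered
  expect_equal(ls[1:2], c(0.02, -0.02), tolerance = 1e-12)
  expect_true(all(is.na(ls[3:12])))
  # raw means differ, confirming the imbalance matters
  raw <- tapply(resid$value, resid$month, mean)
  expect_gt(max(abs(unname(raw) - ls[1:2])), 1e-3)
})

test_that("LSMeans agree with emmeans on unbalanced data", {
  set.seed(10)
  n <- 1800
  resid <- data.frame(
    fish_id = 1:n, sfl_std = runif(n, 80, 250),
    month = sample(1:12, n, TRUE, prob = c(rep(1, 3), rep(5, 9))),
    year = 2010,
    maturity = sample(c("IMMATURE", "MATURE"), n, TRUE, prob = c(0.8, 0.2)),
    area_group = sample(c("WC_MED", "E_MED"), n, TRUE, prob = c(0.85, 0.15)),
    value = rnorm(n, 0.02, 0.1), excluded = FALSE
  )
  m <- fit_condition_model(resid)
  ours <- lsmeans_month(m)
  em <- summary(emmeans::emmeans(m$lm, "month"))$emmean
  expect_equal(ours, em - mean(em), tolerance = 1e-8)
})

test_that("complete confounding raises a rank-deficiency error", {
  resid <- data.frame(
    fish_id = 1:40, sfl_std = 150,
    month = rep(1:2, each = 20), year = 2010,
    maturity = rep(c("IMMATURE", "MATURE"), each = 20),  # aliased with month
    area_group = "WC_MED", value = rnorm(40, 0, 0.1), excluded = FALSE
  )
  expect_error(fit_condition_model(resid, factors = c("month", "maturity"),
                                   include_sfl = FALSE), "rank deficient")
})

test_that("the monthly coefficient table scales LSMeans into the exponent", {
  annual <- power_law_fit(alpha = 3.51e-5, beta = 2.8785)
  expect_equal(monthly_wlr_table(annual, rep(0, 12), 0.01)$beta_by_month,
               rep(2.8785, 12))
  ls <- c(0.5, rep(0, 11))
  tab <- monthly_wlr_table(annual, ls, mse = 0.02)
  expect_equal(tab$beta_by_month[1], 2.8785 + 0.5 * 0.02)
  tab_sqrt <- monthly_wlr_table(annual, ls, mse = 0.02, use_sqrt_mse = TRUE)
  expect_equal(tab_sqrt$beta_by_month[1], 2.8785 + 0.5 * sqrt(0.02))
})

test_that("published monthly coefficients reproduce printed predictions", {
  east <- bft_monthly_wlr("EAST")
  expect_equal(predict_monthly_weight(east, 200, 5),
               3.508e-5 * 200^2.88691388, tolerance = 1e-12)
  expect_equal(predict_monthly_weight(east, 200, 5), 154.2, tolerance = 0.1)
  west <- bft_monthly_wlr("WEST")
  expect_equal(predict_monthly_weight(west, 200, 1),
               1.771e-5 * 200^2.99789075, tolerance = 1e-12)
  expect_equal(predict_monthly_weight(west, 200, 1), 140.1, tolerance = 0.1)
  expect_equal(predict_monthly_weight(east, 1, 3), east$alpha)
  expect_error(predict_monthly_weight(east, 200, 13), "month")
  # seasonal exponents perturb the annual prediction by less than 6%
  annual <- predict_weight(bft_annual_wlr("EAST"), 200)
  monthly <- predict_monthly_weight(east, 200, 1:12)
  expect_true(all(abs(monthly - annual) / annual < 0.06))
})
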