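# Seasonal condition analysis: scaled residuals from the annual
# weight-length fit, a fixed-factor linear model on them, least-squares
# means by month, and the monthly coefficient table.

#' Scaled residuals from a weight-length fit
#'
#' Computes \code{(obs - pred) / pred} for every standardized record, the
#' size-free condition measure (raw residuals grow with fish size). A
#' residual above 1 means the fish weighed more than double its prediction;
#' such values are flagged for exclusion (strictly greater than 1, a value
#' of exactly 1 is retained). Residuals are bounded below by -1 since
#' weights are non-negative. Each residual carries the factors used by the
#' condition model: month, maturity (mature at or above the stock's
#' length-at-full-maturity: 130 cm SFL East, 185 cm West), and area group
#' (East: east Atlantic, west-central Mediterranean including the Strait of
#' Gibraltar, eastern Mediterranean; West: one group).
#'
#' @param records standardized records (need \code{sfl_std}, \code{rwt_std};
#'   rows missing either are skipped with a message).
#' @param fit annual \code{\link{power_law_fit}}.
#' @param maturity_thresholds named cm thresholds per stock.
#' @param area_grouping named character vector mapping area codes to group
#'   labels (default: the package's standard grouping).
#' @return data frame: \code{fish_id}, \code{sfl_std}, \code{month},
#'   \code{year}, \code{maturity}, \code{area_group}, \code{value},
#'   \code{excluded}.
#' @export
scaled_residuals <- function(records, fit,
                             maturity_thresholds = c(EAST = 130, WEST = 185),
                             area_grouping = AREA_GROUPS) {
  ok <- is.finite(records$sfl_std) & is.finite(records$rwt_std)
  if (any(!ok))
    message(sum(!ok), " records lack sfl_std or rwt_std and are skipped")
  rec <- records[ok, , drop = FALSE]
  pred <- predict_weight(fit, rec$sfl_std)
  value <- (rec$rwt_std - pred) / pred
  thr <- maturity_thresholds[as.character(rec$stock)]
  data.frame(
    fish_id = rec$fish_id,
    sfl_std = rec$sfl_std,
    month = as.integer(rec$month),
    year = rec$year,
    maturity = ifelse(rec$sfl_std >= thr, "MATURE", "IMMATURE"),
    area_group = unname(area_grouping[as.character(rec$area)]),
    value = value,
    excluded = value > 1,
    stringsAsFactors = FALSE
  )
}

#' Fixed-factor model of fish condition
#'
#' Ordinary least-squares linear model of the retained scaled residuals on
#' standardized length (continuous) and the chosen fixed factors (month,
#' maturity, area group; year can be added for the deviance diagnostic but
#' is excluded from the final monthly model). Factors use sum-to-zero
#' (effects) coding so factor coefficients are departures from the overall
#' mean and the monthly least-squares means are interpretable as seasonal
#' deviations. Per-factor explained deviance is the Type III (marginal) sum
#' of squares from dropping each term from the full additive model.
#'
#' @param residuals output of \code{\link{scaled_residuals}}; rows flagged
#'   \code{excluded} are removed here.
#' @param factors subset of \code{c("month", "maturity", "area_group",
#'   "year")} to include (each needs at least 2 observed levels).
#' @param include_sfl include \code{sfl_std} as continuous predictor.
#' @return Object of class \code{condition_model}: the \code{lm} fit,
#'   \code{mse} (residual mean square), \code{deviance} (per-term Type III
#'   SS with F statistics), the factor levels, and the data used.
#' @export
fit_condition_model <- function(residuals,
                                factors = c("month", "maturity", "area_group"),
                                include_sfl = TRUE) {
  factors <- match.arg(factors, c("month", "maturity", "area_group", "year"),
                       several.ok = TRUE)
  dat <- residuals[!residuals$excluded, , drop = FALSE]
  for (f in factors) {
    lv <- unique(dat[[f]])
    if (length(lv[!is.na(lv)]) < 2)
      stop_domain("factor ", f, " has fewer than 2 observed levels")
    dat[[f]] <- factor(dat[[f]])
  }
  rhs <- c(if (include_sfl) "sfl_std", factors)
  fml <- stats::as.formula(paste("value ~", paste(rhs, collapse = " + ")))
  contr <- stats::setNames(
    replicate(length(factors), stats::contr.sum, simplify = FALSE), factors)
  fit <- stats::lm(fml, data = dat, contrasts = contr)
  if (any(is.na(stats::coef(fit)))) {
    # aliasing in an additive factor model traces back to empty cells;
    # name them so the caller can regroup or drop a factor
    cells <- character()
    if (length(factors) > 1) {
      counts <- table(dat[factors])
      empty <- which(counts == 0, arr.ind = TRUE)
      cells <- apply(empty, 1, function(i)
        paste(mapply(function(f, k) dimnames(counts)[[f]][k],
                     seq_along(factors), i), collapse = " x "))
    }
    stop_domain("condition model is rank deficient; empty factor cells: ",
                if (length(cells)) paste(cells, collapse = "; ") else "none")
  }
  dev <- stats::drop1(fit, test = "F")
  structure(
    list(lm = fit, mse = summary(fit)$sigma^2,
         deviance = dev, factors = factors, include_sfl = include_sfl,
         data = dat),
    class = "condition_model"
  )
}

#' @export
print.condition_model <- function(x, ...) {
  cat("Condition model: value ~",
      paste(c(if (x$include_sfl) "sfl_std", x$factors), collapse = " + "),
      sprintf("\n  n = %d, MSE = %.6g\n", nrow(x$data), x$mse))
  print(x$deviance)
  invisible(x)
}

#' Monthly least-squares means of condition
#'
#' Model-based mean scaled residual for each month, computed by predicting
#' on a balanced grid: every combination of the other factor levels appears
#' exactly once per month and \code{sfl_std} is fixed at its overall mean,
#' so the unequal monthly sampling by area/maturity does not leak into the
#' monthly means. Values are centered to mean zero across months (their
#' annual mean is the annual fit itself).
#'
#' @param model a \code{\link{condition_model}} including \code{month}.
#' @return numeric vector of 12 centered least-squares means (positions are
#'   months present in the data; absent months are NA).
#' @export
lsmeans_month <- function(model) {
  if (!"month" %in% model$factors)
    stop_domain("model does not include a month factor")
  dat <- model$data
  others <- setdiff(model$factors, "month")
  grid_args <- c(list(month = levels(dat$month)),
                 lapply(dat[others], levels))
  names(grid_args) <- c("month", others)
  grid <- expand.grid(grid_args, stringsAsFactors = FALSE)
  for (f in c("month", others)) grid[[f]] <- factor(grid[[f]],
                                                    levels = levels(dat[[f]]))
  if (model$include_sfl) grid$sfl_std <- mean(dat$sfl_std)
  pred <- stats::predict(model$lm, newdata = grid)
  ls <- tapply(pred, grid$month, mean)
  out <- rep(NA_real_, 12)
  out[as.integer(names(ls))] <- as.numeric(ls)
  present <- !is.na(out)
  out[present] <- out[present] - mean(out[present])
  out
}

#' Monthly weight-length coefficients
#'
#' Container for the monthly relationship
#' \code{RWT_stdM = alpha * SFL_std^beta_m}: one scale coefficient and
#' twelve monthly exponents.
#'
#' @param alpha scale coefficient (kg cm^-beta).
#' @param beta_by_month 12 monthly exponents.
#' @param stock optional stock tag.
#' @export
monthly_wlr <- function(alpha, beta_by_month, stock = NULL) {
  stopifnot(alpha > 0, length(beta_by_month) == 12)
  structure(list(alpha = alpha, beta_by_month = as.numeric(beta_by_month),
                 stock = stock),
            class = "monthly_wlr")
}

#' @export
print.monthly_wlr <- function(x, ...) {
  cat(sprintf("Monthly weight-length coefficients (alpha = %.4g)\n", x$alpha))
  print(data.frame(month = 1:12, beta = x$beta_by_month))
  invisible(x)
}

#' Build the monthly coefficient table from the condition model
#'
#' The month effect enters the weight-length function through the exponent:
#' \code{beta_m = beta_annual + LSMean_m * MSE}, where \code{MSE} is the
#' condition model's residual mean square. \code{use_sqrt_mse = TRUE}
#' substitutes the root mean square error instead (the scaling constant is
#' a modelling convention; both are exposed). \code{alpha} is the annual
#' fit's scale coefficient, unchanged.
#'
#' @param annual annual \code{\link{power_law_fit}}.
#' @param lsmeans 12 monthly least-squares means
#'   (\code{\link{lsmeans_month}}).
#' @param mse condition-model residual mean square.
#' @param use_sqrt_mse scale LSMeans by \code{sqrt(mse)} instead of
#'   \code{mse}.
#' @return a \code{\link{monthly_wlr}}.
#' @export
monthly_wlr_table <- function(annual, lsmeans, mse, use_sqrt_mse = FALSE) {
  stopifnot(length(lsmeans) == 12)
  scale <- if (use_sqrt_mse) sqrt(mse) else mse
  monthly_wlr(alpha = annual$alpha,
              beta_by_month = annual$beta + lsmeans * scale,
              stock = annual$stock)
}

#' Predicted round weight at length for a given month
#'
#' @param monthly a \code{\link{monthly_wlr}}.
#' @param sfl straight fork length, cm (> 0).
#' @param month month 1-12.
#' @return predicted round weight, kg.
#' @export
predict_monthly_weight <- function(monthly, sfl, month) {
  if (any(!month %in% 1:12)) stop_domain("month must be in 1..12")
  if (any(sfl <= 0)) stop_domain("sfl must be positive")
  monthly$alpha * sfl^monthly$beta_by_month[month]
}
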