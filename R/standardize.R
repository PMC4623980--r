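#' Linear conversion between two measurement types
#'
#' Container for a fitted length-length or weight-weight conversion
#' \code{y = alpha + beta * x}. Conversions are always fitted within one
#' stock; Eastern and Western fish are never pooled.
#'
#' @param x_type,y_type measurement-type codes (e.g. \code{"CFL"}, \code{"RWT"}).
#' @param alpha intercept, in units of \code{y}.
#' @param beta slope (dimensionless for length-length and weight-weight pairs).
#' @param r2 squared Pearson correlation of observed vs fitted values.
#' @param residual_se residual standard error \code{sqrt(SSE/(n-2))}, units of y.
#' @param n number of paired observations.
#' @param x_range,y_range observed ranges, length-2 numeric.
#' @param method \code{"ROBUST"} or \code{"OLS"}.
#' @param stock optional stock tag (\code{"EAST"}/\code{"WEST"}).
#' @return An object of class \code{linear_conversion}.
#' @export
linear_conversion <- function(x_type, y_type, alpha, beta, r2, residual_se, n,
                              x_range, y_range, method = c("ROBUST", "OLS"),
                              stock = NULL) {
  method <- match.arg(method)
  stopifnot(n >= 3, r2 >= 0, r2 <= 1,
            all(is.finite(x_range)), all(is.finite(y_range)))
  structure(
    list(x_type = x_type, y_type = y_type, alpha = alpha, beta = beta,
         r2 = r2, residual_se = residual_se, n = n,
         x_range = range(x_range), y_range = range(y_range),
         method = method, stock = stock),
    class = "linear_conversion"
  )
}

#' @export
print.linear_conversion <- function(x, ...) {
  cat(sprintf("%s = %.4f + %.4f x %s  (%s, n = %d, r2 = %.3f, RSE = %.3f)\n",
              x$y_type, x$alpha, x$beta, x$x_type,
              x$method, x$n, x$r2, x$residual_se))
  invisible(x)
}

#' @export
predict.linear_conversion <- function(object, x, ...) {
  object$alpha + object$beta * x
}

#' Fit a linear measurement conversion
#'
#' Fits \code{y = alpha + beta * x} either by ordinary least squares or by
#' robust iteratively reweighted least squares with the Tukey bisquare
#' psi-function (tuning constant 4.685, start at the OLS solution, residual
#' scale re-estimated each iteration by the MAD). Iteration stops when the
#' largest relative coefficient change drops below 1e-8 or after 50
#' iterations. The reported r-square is the squared Pearson correlation of
#' observed against fitted values and the residual standard error is
#' computed from the unweighted residuals of the final coefficients.
#'
#' @param x,y paired positive measurements (same length, >= 3 pairs).
#' @param method \code{"ROBUST"} (default) or \code{"OLS"}.
#' @param x_type,y_type measurement-type labels stored with the fit.
#' @param stock optional stock tag.
#' @return A \code{\link{linear_conversion}}.
#' @examples
#' fit_linear_conversion(1:10, 2 + 3 * (1:10), x_type = "SFL", y_type = "CFL")
#' @export
fit_linear_conversion <- function(x, y, method = c("ROBUST", "OLS"),
                                  x_type = "x", y_type = "y", stock = NULL) {
  method <- match.arg(method)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop_domain("need at least 3 paired observations, got ", n)
  if (any(x <= 0) || any(y <= 0)) stop_domain("measurements must be positive")
  if (stats::var(x) == 0) stop_domain("zero variance in x: conversion not identifiable")

  X <- cbind(1, x)
  coef <- stats::lm.fit(X, y)$coefficients
  if (method == "ROBUST") {
    cc <- 4.685
    for (iter in seq_len(50)) {
      r <- as.numeric(y - X %*% coef)
      s <- stats::median(abs(r)) / 0.6745
      if (s <= 0) break  # exact fit: weights degenerate, OLS solution stands
      u <- pmin(abs(r / (cc * s)), 1)
      w <- (1 - u^2)^2
      new_coef <- stats::lm.wfit(X, y, w)$coefficients
      delta <- max(abs(new_coef - coef) / pmax(abs(coef), 1e-12))
      coef <- new_coef
      if (delta < 1e-8) break
    }
  }

  fitted <- as.numeric(X %*% coef)
  res <- y - fitted
  r2 <- if (stats::var(fitted) == 0) 1 else stats::cor(y, fitted)^2
  linear_conversion(
    x_type = x_type, y_type = y_type,
    alpha = unname(coef[1]), beta = unname(coef[2]),
    r2 = r2, residual_se = sqrt(sum(res^2) / (n - 2)), n = n,
    x_range = range(x), y_range = range(y), method = method, stock = stock
  )
}

# Conversion pairs fitted per stock, in the direction needed for
# standardization (observed type -> standard type) plus the reverse.
default_conversion_pairs <- function(stock) {
  if (stock == "EAST") {
    list(c("CFL", "SFL"), c("SFL", "CFL"),
         c("GWT", "RWT"), c("RWT", "GWT"),
         c("GGWT", "RWT"), c("RWT", "GGWT"))
  } else {
    list(c("CFL", "SFL"), c("SFL", "CFL"),
         c("DWT", "RWT"), c("RWT", "DWT"))
  }
}

#' Fit all measurement conversions available in a set of records
#'
#' Scans the records of one stock for fish carrying both members of each
#' conversion pair and fits each pair by \code{\link{fit_linear_conversion}}.
#' Pairs with fewer than \code{min_n} dual-measured fish are skipped.
#'
#' @param records a fish-record data frame (see \code{\link{simulate_fishery}}).
#' @param stock \code{"EAST"} or \code{"WEST"}; defaults to the records' stock.
#' @param pairs list of \code{c(x_type, y_type)} pairs; defaults to the
#'   stock's standardization pairs in both directions.
#' @param method passed to \code{\link{fit_linear_conversion}}.
#' @param min_n minimum number of dual-measured fish per pair.
#' @return A list of \code{\link{linear_conversion}} objects named
#'   \code{"<x>-><y>"}.
#' @export
fit_stock_conversions <- function(records, stock = NULL, pairs = NULL,
                                  method = "ROBUST", min_n = 10) {
  stock <- stock %||% unique(records$stock)[1]
  pairs <- pairs %||% default_conversion_pairs(stock)
  out <- list()
  for (p in pairs) {
    xs <- records[[measurement_column(p[1])]]
    ys <- records[[measurement_column(p[2])]]
    ok <- is.finite(xs) & is.finite(ys) & xs > 0 & ys > 0
    if (sum(ok) < min_n) next
    key <- paste0(p[1], "->", p[2])
    out[[key]] <- fit_linear_conversion(xs[ok], ys[ok], method = method,
                                        x_type = p[1], y_type = p[2],
                                        stock = stock)
  }
  out
}

find_conversion <- function(conversions, x_type, y_type) {
  for (cv in conversions) {
    if (cv$x_type == x_type && cv$y_type == y_type) return(cv)
  }
  NULL
}

#' Standardize mixed-type records to common length and weight units
#'
#' Converts every record to straight fork length (\code{sfl_std}, cm) and
#' round weight (\code{rwt_std}, kg). A measured SFL or RWT is always taken
#' as-is. Otherwise a conversion is applied only if its coefficient of
#' determination passes the gate (default r-square >= 0.98): for length,
#' CFL to SFL; for weight, in priority order GWT then GGWT to RWT in the
#' East and DWT to RWT in the West. GWT is preferred over GGWT because it is
#' the less-processed state, closest to round weight. A conversion failing
#' the gate is refused with a message, never silently applied; the lengths
#' LD1, HeadL and PreopL are never used for standardization. Records where
#' neither quantity is obtainable are dropped.
#'
#' @param records fish-record data frame.
#' @param conversions list of \code{\link{linear_conversion}} objects
#'   (e.g. from \code{\link{fit_stock_conversions}} or
#'   \code{\link{bft_conversion}}).
#' @param gate minimum r-square for a conversion to be used.
#' @param pre_filter if \code{TRUE}, converted values whose source pair sits
#'   more than 5 fitted residual SEs off the conversion line are flagged as
#'   missing (an optional gross-error screen, off by default).
#' @return A data frame with columns \code{fish_id}, \code{stock},
#'   \code{area}, \code{gear}, \code{year}, \code{month}, \code{sfl_std},
#'   \code{rwt_std}, \code{sfl_source}, \code{rwt_source} (plus latent-truth
#'   columns when present in the input). Sources are \code{"MEASURED"} or
#'   \code{"CONVERTED(<type>)"}.
#' @export
standardize_records <- function(records, conversions, gate = 0.98,
                                pre_filter = FALSE) {
  n <- nrow(records)
  sfl <- records$sfl_cm %||% rep(NA_real_, n)
  rwt <- records$rwt_kg %||% rep(NA_real_, n)
  sfl_std <- ifelse(is.finite(sfl), sfl, NA_real_)
  rwt_std <- ifelse(is.finite(rwt), rwt, NA_real_)
  sfl_source <- ifelse(is.finite(sfl), "MEASURED", NA_character_)
  rwt_source <- ifelse(is.finite(rwt), "MEASURED", NA_character_)

  apply_conversion <- function(std, src, from_type, to_type) {
    cvn <- find_conversion(conversions, from_type, to_type)
    if (is.null(cvn)) return(list(std = std, src = src))
    if (cvn$r2 < gate) {
      message(sprintf("conversion %s->%s refused: r2 = %.3f below gate %.3f",
                      from_type, to_type, cvn$r2, gate))
      return(list(std = std, src = src))
    }
    raw <- records[[measurement_column(from_type)]]
    use <- is.na(std) & is.finite(raw)
    if (any(use)) {
      std[use] <- predict(cvn, raw[use])
      src[use] <- paste0("CONVERTED(", from_type, ")")
    }
    list(std = std, src = src)
  }

  stock <- unique(records$stock)[1]
  len <- apply_conversion(sfl_std, sfl_source, "CFL", "SFL")
  sfl_std <- len$std; sfl_source <- len$src
  weight_priority <- if (identical(stock, "WEST")) "DWT" else c("GWT", "GGWT")
  for (wt in weight_priority) {
    w <- apply_conversion(rwt_std, rwt_source, wt, "RWT")
    rwt_std <- w$std; rwt_source <- w$src
  }

  if (pre_filter) {
    # Optional gross-error screen on converted weights: a converted value is
    # dropped when no plausible source reading could sit within 5 residual
    # SEs of the conversion line. Standardization itself removes no outliers.
    for (wt in weight_priority) {
      cvn <- find_conversion(conversions, wt, "RWT")
      if (is.null(cvn) || cvn$r2 < gate) next
      raw <- records[[measurement_column(wt)]]
      pred <- predict(cvn, raw)
      bad <- is.finite(raw) & rwt_source == paste0("CONVERTED(", wt, ")") &
        abs(rwt_std - pred) > 5 * cvn$residual_se
      rwt_std[which(bad)] <- NA_real_
      rwt_source[which(bad)] <- NA_character_
    }
  }

  out <- data.frame(
    fish_id = records$fish_id, stock = records$stock, area = records$area,
    gear = records$gear, year = records$year, month = records$month,
    sfl_std = sfl_std, rwt_std = rwt_std,
    sfl_source = sfl_source, rwt_source = rwt_source,
    stringsAsFactors = FALSE
  )
  for (latent in c("true_sfl", "true_rwt")) {
    if (!is.null(records[[latent]])) out[[latent]] <- records[[latent]]
  }
  out[!is.na(out$sfl_std) | !is.na(out$rwt_std), , drop = FALSE]
}

#' Records usable for weight-length fitting
#'
#' Subset of standardized records with both a standardized length and a
#' standardized weight.
#' @param standardized output of \code{\link{standardize_records}}.
#' @export
wlr_input <- function(standardized) {
  standardized[is.finite(standardized$sfl_std) &
                 is.finite(standardized$rwt_std), , drop = FALSE]
}
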