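#' Coefficient of variation of weight at length in 5 cm bins
#'
#' Bins records by standardized straight fork length into half-open
#' \code{[L, L + bin_width)} bins anchored at 0 cm and computes the sample
#' mean, SD (n-1 denominator) and CV of standardized round weight per bin.
#' Bins holding fewer than \code{min_count} fish are flagged and their CV
#' imputed with the mean CV of the well-populated bins, so every fish can be
#' assigned an inverse-CV weight.
#'
#' @param records data frame with \code{sfl_std} and \code{rwt_std}.
#' @param bin_width bin width in cm (default 5).
#' @param min_count minimum fish per bin for the bin's own CV to be used.
#' @return A data frame of class \code{bin_cv}: \code{bin_lower}, \code{n},
#'   \code{mean_w}, \code{sd_w}, \code{cv}, \code{imputed}. Attribute
#'   \code{mean_cv} carries the stock-wide mean CV used for imputation.
#' @export
bin_cv_profile <- function(records, bin_width = 5, min_count = 10) {
  ok <- is.finite(records$sfl_std) & is.finite(records$rwt_std)
  sfl <- records$sfl_std[ok]; rwt <- records$rwt_std[ok]
  if (length(sfl) == 0) {
    out <- data.frame(bin_lower = numeric(), n = integer(), mean_w = numeric(),
                      sd_w = numeric(), cv = numeric(), imputed = logical())
    class(out) <- c("bin_cv", "data.frame")
    attr(out, "bin_width") <- bin_width
    return(out)
  }
  bin <- floor(sfl / bin_width) * bin_width
  lowers <- sort(unique(bin))
  n <- as.integer(tapply(rwt, bin, length)[as.character(lowers)])
  mean_w <- as.numeric(tapply(rwt, bin, mean)[as.character(lowers)])
  sd_w <- as.numeric(tapply(rwt, bin, stats::sd)[as.character(lowers)])
  cv <- ifelse(n >= 2 & mean_w > 0, sd_w / mean_w, NA_real_)
  sparse <- n < min_count | !is.finite(cv)
  mean_cv <- mean(cv[!sparse])
  cv_out <- ifelse(sparse, mean_cv, cv)
  out <- data.frame(bin_lower = lowers, n = n, mean_w = mean_w, sd_w = sd_w,
                    cv = cv_out, imputed = sparse)
  class(out) <- c("bin_cv", "data.frame")
  attr(out, "bin_width") <- bin_width
  attr(out, "mean_cv") <- mean_cv
  out
}

# Per-fish weight from a bin CV profile: 1/cv^cv_power, cv looked up by bin.
# Lengths falling outside the profiled bins get the stock-wide mean CV.
cv_weights <- function(sfl, profile, cv_power = 1) {
  bw <- attr(profile, "bin_width") %||% 5
  bin <- floor(sfl / bw) * bw
  cv <- profile$cv[match(bin, profile$bin_lower)]
  cv[!is.finite(cv)] <- attr(profile, "mean_cv") %||% mean(profile$cv, na.rm = TRUE)
  1 / cv^cv_power
}

#' Power-law fit container
#' @keywords internal
#' @export
power_law_fit <- function(alpha, beta, weighting = "NONE", n = NA_integer_,
                          residual_se = NA_real_, aic = NA_real_,
                          rmse = NA_real_, param_cov = NULL,
                          converged = TRUE, iterations = NA_integer_,
                          stock = NULL) {
  stopifnot(alpha > 0, beta > 1, beta < 5)
  structure(
    list(alpha = alpha, beta = beta, weighting = weighting, n = n,
         residual_se = residual_se, aic = aic, rmse = rmse,
         param_cov = param_cov, converged = converged,
         iterations = iterations, stock = stock),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("W = %.4g x L^%.4f  (weighting %s, n = %s, RMSE = %.3f, converged: %s)\n",
              x$alpha, x$beta, x$weighting,
              format(x$n), x$rmse, x$converged))
  invisible(x)
}

#' Fit the allometric weight-length power law
#'
#' Fits \code{W = alpha * L^beta} by minimizing the (optionally weighted)
#' sum of squares \code{sum(w * (W - alpha * L^beta)^2)} with Gauss-Newton
#' iteration, started at the log-log OLS estimate. Under \code{"INV_CV"}
#' weighting each fish's weight is the inverse of the CV of weight at length
#' in its 5 cm bin, so highly variable sizes influence the fit less; this is
#' the heteroscedasticity treatment appropriate for allometric data, where
#' the variance of weight grows with length. Iteration stops when the
#' relative change in weighted SSE falls below 1e-10 or after 100
#' iterations; a step-halving line search guards against overshooting. AIC
#' (Gaussian likelihood) and RMSE are reported on unweighted residuals.
#'
#' @param sfl,rwt standardized lengths (cm) and weights (kg); alternatively
#'   pass a standardized data frame as \code{sfl} and leave \code{rwt} missing.
#' @param weighting \code{"NONE"} or \code{"INV_CV"}.
#' @param cv_profile optional \code{\link{bin_cv_profile}} result; computed
#'   from the data when omitted and needed.
#' @param cv_power exponent on 1/CV in the weights: 1 uses 1/CV exactly as
#'   the weighting factor (default); 2 gives classical inverse-variance-style
#'   1/CV^2 weights.
#' @param min_bins minimum number of distinct 5 cm bins required.
#' @return A \code{\link{power_law_fit}} with parameter covariance from the
#'   weighted Jacobian; non-convergence is flagged, never silent.
#' @examples
#' l <- seq(40, 250, by = 1)
#' f <- fit_power_law(l, 2e-5 * l^3)
#' predict_weight(f, 100)
#' @export
fit_power_law <- function(sfl, rwt = NULL, weighting = c("NONE", "INV_CV"),
                          cv_profile = NULL, cv_power = 1, min_bins = 3) {
  weighting <- match.arg(weighting)
  if (is.data.frame(sfl)) {
    df <- wlr_input(sfl)
    stock <- unique(df$stock)[1]
    rwt <- df$rwt_std; sfl <- df$sfl_std
  } else stock <- NULL
  ok <- is.finite(sfl) & is.finite(rwt)
  sfl <- sfl[ok]; rwt <- rwt[ok]
  if (any(sfl <= 0) || any(rwt <= 0))
    stop_domain("lengths and weights must be positive")
  n <- length(sfl)
  if (n < 10) stop_domain("need at least 10 records, got ", n)
  if (length(unique(floor(sfl / 5))) < min_bins)
    stop_domain("records must span at least ", min_bins, " 5 cm bins")

  w <- rep(1, n)
  if (weighting == "INV_CV") {
    if (is.null(cv_profile))
      cv_profile <- bin_cv_profile(data.frame(sfl_std = sfl, rwt_std = rwt))
    w <- cv_weights(sfl, cv_profile, cv_power)
  }

  # log-log OLS start
  ll <- stats::lm.fit(cbind(1, log(sfl)), log(rwt))$coefficients
  alpha <- exp(ll[1]); beta <- ll[2]
  logl <- log(sfl)

  sse <- function(a, b) sum(w * (rwt - a * sfl^b)^2)
  s_old <- sse(alpha, beta)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(100)) {
    iters <- it
    mu <- alpha * sfl^beta
    r <- rwt - mu
    # Jacobian of mu wrt (alpha, beta)
    j1 <- mu / alpha
    j2 <- mu * logl
    a11 <- sum(w * j1 * j1); a12 <- sum(w * j1 * j2); a22 <- sum(w * j2 * j2)
    g1 <- sum(w * j1 * r); g2 <- sum(w * j2 * r)
    det <- a11 * a22 - a12^2
    if (!is.finite(det) || det <= 0) break
    d_alpha <- (a22 * g1 - a12 * g2) / det
    d_beta <- (a11 * g2 - a12 * g1) / det
    step <- 1
    repeat {
      a_new <- alpha + step * d_alpha
      b_new <- beta + step * d_beta
      if (a_new > 0 && is.finite(sse(a_new, b_new)) &&
          sse(a_new, b_new) <= s_old) break
      step <- step / 2
      if (step < 1e-10) { a_new <- alpha; b_new <- beta; break }
    }
    s_new <- sse(a_new, b_new)
    rel <- abs(s_old - s_new) / max(s_old, .Machine$double.eps)
    alpha <- a_new; beta <- b_new; s_old <- s_new
    if (rel < 1e-10) { converged <- TRUE; break }
  }

  mu <- alpha * sfl^beta
  res <- rwt - mu
  j1 <- mu / alpha; j2 <- mu * logl
  jtj <- matrix(c(sum(w * j1 * j1), sum(w * j1 * j2),
                  sum(w * j1 * j2), sum(w * j2 * j2)), 2, 2)
  s2w <- s_old / (n - 2)
  param_cov <- tryCatch(s2w * solve(jtj), error = function(e) NULL)
  rss <- sum(res^2)
  aic <- n * log(2 * pi) + n * log(rss / n) + n + 2 * 3  # 2 params + sigma
  power_law_fit(
    alpha = unname(alpha), beta = unname(beta), weighting = weighting, n = n,
    residual_se = sqrt(rss / (n - 2)), aic = aic,
    rmse = sqrt(mean(res^2)), param_cov = param_cov,
    converged = converged, iterations = iters, stock = stock
  )
}

#' Predicted round weight at length
#'
#' @param fit a \code{\link{power_law_fit}} (or any list with \code{alpha}
#'   and \code{beta}).
#' @param sfl straight fork length in cm, positive.
#' @return predicted round weight in kg, \code{alpha * sfl^beta}.
#' @export
predict_weight <- function(fit, sfl) {
  if (any(!is.finite(sfl)) || any(sfl <= 0))
    stop_domain("sfl must be positive")
  fit$alpha * sfl^fit$beta
}

#' Nonlinear quantile fit of the weight-length power law
#'
#' Estimates the tau-th conditional quantile curve
#' \code{Q_tau(W | L) = alpha * L^beta} by minimizing the pinball
#' (check) loss \code{sum(rho_tau(W - alpha * L^beta))}. Because the loss is
#' non-smooth, the search is derivative-free Nelder-Mead over
#' \code{(log alpha, beta)}, started at the least-squares solution and
#' restarted once from its own optimum (tolerance 1e-8 on the loss).
#' Quantile curves describe the distribution of weight at a given length
#' and are less sensitive to extreme weights than the mean fit.
#'
#' @param sfl,rwt standardized lengths and weights (or a standardized data
#'   frame as \code{sfl}).
#' @param tau quantile level in (0, 1).
#' @param start optional \code{\link{power_law_fit}} to start from.
#' @return An object of class \code{quantile_fit}: \code{tau}, \code{alpha},
#'   \code{beta}, \code{pinball_loss}.
#' @export
fit_power_quantile <- function(sfl, rwt = NULL, tau = 0.5, start = NULL) {
  if (tau <= 0 || tau >= 1) stop_domain("tau must lie strictly in (0, 1)")
  if (is.data.frame(sfl)) {
    df <- wlr_input(sfl); rwt <- df$rwt_std; sfl <- df$sfl_std
  }
  ok <- is.finite(sfl) & is.finite(rwt)
  sfl <- sfl[ok]; rwt <- rwt[ok]
  if (length(sfl) < 50) stop_domain("need at least 50 records for a quantile fit")
  if (is.null(start)) start <- fit_power_law(sfl, rwt)
  pinball <- function(par) {
    r <- rwt - exp(par[1]) * sfl^par[2]
    sum(r * (tau - (r < 0)))
  }
  par <- c(log(start$alpha), start$beta)
  for (k in 1:2) {
    opt <- stats::optim(par, pinball, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-8))
    par <- opt$par
  }
  structure(list(tau = tau, alpha = exp(par[1]), beta = par[2],
                 pinball_loss = opt$value),
            class = "quantile_fit")
}

#' @export
print.quantile_fit <- function(x, ...) {
  cat(sprintf("tau = %.3f: W = %.4g x L^%.4f (pinball loss %.4g)\n",
              x$tau, x$alpha, x$beta, x$pinball_loss))
  invisible(x)
}

#' Bootstrap the weight-length fit
#'
#' Two nonparametric resampling schemes around \code{\link{fit_power_law}}:
#' \describe{
#'   \item{EQUAL_PROB}{each replicate resamples n fish from n with equal
#'     probability and replacement — the ordinary bootstrap, quantifying
#'     parameter uncertainty under the observed size composition.}
#'   \item{UNIFORM_PER_BIN}{each replicate draws \code{m_per_bin} fish with
#'     replacement from every non-empty 5 cm bin inside \code{bin_range} —
#'     a what-if design in which every size class contributes equally,
#'     used to probe the effect of the unbalanced size sampling.}
#' }
#' Each replicate is refit with the same weighting scheme (the bin CV
#' profile is recomputed from the replicate's own data) and the replicate
#' parameter distributions are summarized.
#'
#' @param sfl,rwt standardized lengths/weights (or a standardized data frame
#'   as \code{sfl}).
#' @param scheme \code{"EQUAL_PROB"} or \code{"UNIFORM_PER_BIN"}.
#' @param B number of replicates (the headline analyses use 1000).
#' @param seed integer seed for the resampling stream.
#' @param weighting,cv_power passed to \code{\link{fit_power_law}}.
#' @param m_per_bin samples per bin under \code{UNIFORM_PER_BIN}.
#' @param bin_range size range (cm) whose bins are resampled under
#'   \code{UNIFORM_PER_BIN}.
#' @return Object of class \code{bootstrap_result}: \code{scheme}, \code{B},
#'   \code{replicates} (data frame of alpha, beta, rmse), \code{point}
#'   (the full-data fit) and \code{summary} (mean, bias, percentile CI and
#'   skewness per parameter).
#' @export
bootstrap_wlr <- function(sfl, rwt = NULL,
                          scheme = c("EQUAL_PROB", "UNIFORM_PER_BIN"),
                          B = 1000, seed = 1, weighting = "INV_CV",
                          cv_power = 1, m_per_bin = 100,
                          bin_range = c(30, 300)) {
  scheme <- match.arg(scheme)
  if (is.data.frame(sfl)) {
    df <- wlr_input(sfl); rwt <- df$rwt_std; sfl <- df$sfl_std
  }
  ok <- is.finite(sfl) & is.finite(rwt)
  sfl <- sfl[ok]; rwt <- rwt[ok]
  n <- length(sfl)
  point <- fit_power_law(sfl, rwt, weighting = weighting, cv_power = cv_power)

  bin_members <- NULL
  if (scheme == "UNIFORM_PER_BIN") {
    bin <- floor(sfl / 5) * 5
    keep <- bin >= bin_range[1] & bin < bin_range[2]
    bin_members <- split(which(keep), bin[keep])
    if (length(bin_members) == 0)
      stop_domain("no non-empty 5 cm bins inside bin_range")
  }

  reps <- with_seed(seed, {
    out <- matrix(NA_real_, B, 3, dimnames = list(NULL, c("alpha", "beta", "rmse")))
    for (b in seq_len(B)) {
      idx <- if (scheme == "EQUAL_PROB") {
        sample.int(n, n, replace = TRUE)
      } else {
        unlist(lapply(bin_members, function(m)
          m[sample.int(length(m), m_per_bin, replace = TRUE)]),
          use.names = FALSE)
      }
      fit <- fit_power_law(sfl[idx], rwt[idx], weighting = weighting,
                           cv_power = cv_power)
      out[b, ] <- c(fit$alpha, fit$beta, fit$rmse)
    }
    out
  })

  reps <- as.data.frame(reps)
  summarize <- function(v, hat) {
    c(mean = mean(v), bias = mean(v) - hat,
      ci_lower = unname(stats::quantile(v, 0.025)),
      ci_upper = unname(stats::quantile(v, 0.975)),
      skewness = skewness(v))
  }
  structure(
    list(scheme = scheme, B = B, seed = seed, weighting = weighting,
         replicates = reps, point = point,
         summary = list(alpha = summarize(reps$alpha, point$alpha),
                        beta = summarize(reps$beta, point$beta),
                        rmse = summarize(reps$rmse, point$rmse))),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("%s bootstrap, B = %d (weighting %s)\n", x$scheme, x$B, x$weighting))
  for (p in c("alpha", "beta", "rmse")) {
    s <- x$summary[[p]]
    cat(sprintf("  %-5s mean %.6g  bias %.2g  95%% CI [%.6g, %.6g]  skew %.3f\n",
                p, s["mean"], s["bias"], s["ci_lower"], s["ci_upper"],
                s["skewness"]))
  }
  invisible(x)
}

#' Percent weight difference between two weight-length fits
#'
#' Evaluates both curves on a length grid and reports the percent difference
#' \code{100 * (W_a - W_b) / W_denominator} per grid point, plus the mean
#' absolute percent difference as the overall summary.
#'
#' @param fit_a,fit_b power-law fits (e.g. the two stocks').
#' @param grid SFL grid in cm, positive.
#' @param denominator which curve scales the difference: \code{"A"} or
#'   \code{"B"}.
#' @return A list with the per-size data frame (\code{sfl}, \code{w_a},
#'   \code{w_b}, \code{pct_diff}) and \code{mean_abs_pct_diff}.
#' @export
compare_wlrs <- function(fit_a, fit_b, grid = seq(60, 280, by = 10),
                         denominator = c("B", "A")) {
  denominator <- match.arg(denominator)
  if (any(grid <= 0)) stop_domain("grid lengths must be positive")
  wa <- predict_weight(fit_a, grid)
  wb <- predict_weight(fit_b, grid)
  den <- if (denominator == "A") wa else wb
  pct <- 100 * (wa - wb) / den
  list(table = data.frame(sfl = grid, w_a = wa, w_b = wb, pct_diff = pct),
       mean_abs_pct_diff = mean(abs(pct)), denominator = denominator)
}

#' Divergence of a fixed conversion factor from a fitted linear conversion
#'
#' Management bodies often convert processed to round weight with a single
#' multiplier. This compares such a factor against a fitted linear
#' conversion at a given processed weight:
#' \code{100 * |(alpha + beta * x) - factor * x| / (alpha + beta * x)}.
#'
#' @param linear a \code{\link{linear_conversion}} (x = processed weight,
#'   y = round weight).
#' @param factor dimensionless multiplier.
#' @param x processed weight(s), kg. Values outside the conversion's fitted
#'   range trigger a warning but are still evaluated.
#' @return percent divergence, same length as \code{x}.
#' @export
compare_fixed_factor <- function(linear, factor, x) {
  if (any(x < linear$x_range[1] | x > linear$x_range[2]))
    warning("x outside the conversion's fitted range [",
            linear$x_range[1], ", ", linear$x_range[2], "]")
  pred <- predict(linear, x)
  100 * abs(pred - factor * x) / pred
}
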