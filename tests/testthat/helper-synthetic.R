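# Shared fixtures, built in code. The cached standardized dataset is reused
# across test files to keep the suite fast.

.fixture_cache <- new.env(parent = emptyenv())

# Full generator -> conversions -> standardization chain for one stock.
synthetic_std <- function(n = 6000, seed = 11, stock = "EAST") {
  key <- paste(stock, n, seed, sep = "_")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cfg <- generator_config(stock, n_fish = 1, seed = seed)
  rec <- suppressMessages(simulate_fishery(cfg, target_records = n))
  conv <- suppressMessages(fit_stock_conversions(rec, stock))
  std <- suppressMessages(standardize_records(rec, conv))
  .fixture_cache[[key]] <- std
  std
}

# Plain heteroscedastic power-law data: lengths uniform on a range,
# multiplicative lognormal weight noise with constant CV.
make_power_data <- function(n, alpha = 2e-5, beta = 3, cv = 0.1,
                            l_range = c(40, 280), seed = 1) {
  set.seed(seed)
  l <- runif(n, l_range[1], l_range[2])
  sigma <- sqrt(log(1 + cv^2))
  w <- alpha * l^beta * exp(rnorm(n, 0, sigma))
  data.frame(sfl = l, rwt = w)
}

# Exact brute-force linear quantile fit of log(w) on log(l): in general
# position the optimal pinball line passes through two data points, so
# enumerating all pairs is an exact oracle.
brute_quantile_loglinear <- function(l, w, tau) {
  x <- log(l); y <- log(w)
  n <- length(x)
  best <- c(NA, NA); best_loss <- Inf
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    ok <- x[j] != x[i]
    j <- j[ok]
    if (!length(j)) next
    b <- (y[j] - y[i]) / (x[j] - x[i])
    a <- y[i] - b * x[i]
    # residual matrix: rows observations, cols candidate lines
    r <- outer(y, rep(1, length(j))) - outer(rep(1, n), a) -
      outer(x, b)
    loss <- colSums(r * (tau - (r < 0)))
    k <- which.min(loss)
    if (loss[k] < best_loss) {
      best_loss <- loss[k]
      best <- c(a[k], b[k])
    }
  }
  list(alpha = exp(best[1]), beta = best[2], loss = best_loss)
}

# Exact linear quantile fit of log(w) on log(l) by one-point exchange.
# The quantile-regression LP has vertex solutions through two data points;
# simplex moves between adjacent vertices swap one active point, and a
# vertex with no improving adjacent swap is the global LP optimum. Scales
# to n where full pair enumeration cannot.
exchange_quantile_loglinear <- function(l, w, tau, max_sweeps = 200) {
  x <- log(l); y <- log(w)
  n <- length(x)
  loss_through <- function(p, ks) {
    out <- numeric(length(ks))
    for (chunk in split(seq_along(ks), ceiling(seq_along(ks) / 500))) {
      kk <- ks[chunk]
      b <- (y[kk] - y[p]) / (x[kk] - x[p])
      a <- y[p] - b * x[p]
      r <- matrix(y, n, length(kk)) -
        matrix(a, n, length(kk), byrow = TRUE) - outer(x, b)
      out[chunk] <- colSums(r * (tau - (r < 0)))
    }
    out
  }
  i <- which.min(x); j <- which.max(x)
  b <- (y[j] - y[i]) / (x[j] - x[i])
  r <- y - (y[i] - b * x[i]) - b * x
  best <- sum(r * (tau - (r < 0)))
  for (s in seq_len(max_sweeps)) {
    improved <- FALSE
    ks <- which(x != x[i] & seq_len(n) != i)
    li <- loss_through(i, ks)
    if (min(li) < best - 1e-12) {
      j <- ks[which.min(li)]; best <- min(li); improved <- TRUE
    }
    ks <- which(x != x[j] & seq_len(n) != j)
    lj <- loss_through(j, ks)
    if (min(lj) < best - 1e-12) {
      i <- ks[which.min(lj)]; best <- min(lj); improved <- TRUE
    }
    if (!improved) break
  }
  b <- (y[j] - y[i]) / (x[j] - x[i])
  a <- y[i] - b * x[i]
  list(alpha = exp(a), beta = b, loss = best)
}

# Size-imbalanced dataset with a distinct heavy regime for the very largest
# fish (above 280 cm), used for the resampling-scheme comparison: the
# uniform-per-bin scheme resamples only 30-300 cm bins, so the fish beyond
# 300 cm anchor only the equal-probability fit.
make_regime_shift_data <- function(n = 8000, seed = 1) {
  set.seed(seed)
  l <- c(runif(0.9 * n, 40, 100), runif(0.1 * n, 240, 360))
  bump <- ifelse(l > 280, 0.8 * (log(l) - log(280)), 0)
  w <- 3.5e-5 * l^2.8 * exp(bump) *
    exp(rnorm(length(l), 0, sqrt(log(1 + 0.12^2))))
  data.frame(sfl = l, rwt = w)
}

# Mean absolute residual of the bootstrap-mean predicted curve on a subset.
bootstrap_curve_mar <- function(boot, sfl, rwt, idx) {
  pred <- vapply(idx, function(i)
    mean(boot$replicates$alpha * sfl[i]^boot$replicates$beta), 0)
  mean(abs(rwt[idx] - pred))
}

# Weighted SSE of a power-law curve, for grid oracles.
weighted_sse <- function(alpha, beta, sfl, rwt, w) {
  sum(w * (rwt - alpha * sfl^beta)^2)
}
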