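#' Age-structured population model
#'
#' Describes a bluefin-like population by its age range, instantaneous
#' natural (and optional fishing) mortality at age, mean length-at-age and
#' a common coefficient of variation of length at age. Mean lengths may be
#' given as a vector or as von Bertalanffy parameters
#' \code{list(l_inf, k, t0)} with \code{L(a) = l_inf * (1 - exp(-k (a - t0)))}.
#'
#' @param ages integer vector of ages (e.g. \code{1:20}).
#' @param M natural mortality at age, 1/yr; scalar or per-age vector, all > 0.
#' @param growth mean length-at-age: numeric vector (cm, one per age,
#'   strictly increasing) or a von Bertalanffy triple.
#' @param length_cv CV of length at age (default 0.125, the value used for
#'   the representativeness simulations).
#' @param F fishing mortality at age, 1/yr (default 0: an unfished
#'   population, the base case for expected sampling).
#' @param plus_group if \code{TRUE} the oldest age is a plus-group closed by
#'   the geometric survivorship sum.
#' @return An object of class \code{population_model}.
#' @export
population_model <- function(ages, M, growth, length_cv = 0.125, F = 0,
                             plus_group = TRUE) {
  ages <- as.integer(ages)
  A <- length(ages)
  if (length(M) == 1) M <- rep(M, A)
  if (length(F) == 1) F <- rep(F, A)
  stopifnot(length(M) == A, length(F) == A, all(M >= 0), all(F >= 0),
            length_cv > 0)
  mean_length <- if (is.list(growth)) {
    growth$l_inf * (1 - exp(-growth$k * (ages - growth$t0)))
  } else {
    stopifnot(length(growth) == A)
    as.numeric(growth)
  }
  if (any(diff(mean_length) <= 0))
    stop_domain("mean length-at-age must be strictly increasing")
  if (any(mean_length <= 0)) stop_domain("mean length-at-age must be positive")
  structure(list(ages = ages, M = M, F = F, mean_length = mean_length,
                 length_cv = length_cv, plus_group = plus_group),
            class = "population_model")
}

#' Survivorship proportions at age
#'
#' Numbers-at-age of a cohort under total mortality \code{Z = M + F}:
#' \code{N_1 = 1}, \code{N_(a+1) = N_a exp(-Z_a)}. When the model carries a
#' plus-group, the terminal class additionally receives the geometric
#' closure \code{N_A exp(-Z_A) / (1 - exp(-Z_A))}, i.e. all ages beyond A.
#' Returned normalized to proportions.
#'
#' @param model a \code{\link{population_model}}.
#' @return named numeric vector of proportions at age, summing to 1.
#' @export
survivorship <- function(model) {
  Z <- model$M + model$F
  A <- length(model$ages)
  N <- numeric(A)
  N[1] <- 1
  if (A > 1) for (a in 2:A) N[a] <- N[a - 1] * exp(-Z[a - 1])
  if (model$plus_group) {
    if (Z[A] <= 0) stop_domain("non-positive terminal Z: plus-group sum diverges")
    N[A] <- N[A] + N[A] * exp(-Z[A]) / (1 - exp(-Z[A]))
  }
  stats::setNames(N / sum(N), model$ages)
}

#' Expected size-sampling distribution of a population
#'
#' Expected proportion of fish per 1 cm straight-fork-length bin if the
#' population were sampled with a non-selective gear: each age contributes
#' a Normal(mean length-at-age, cv * mean) component weighted by its
#' survivorship, integrated over each bin \code{[l, l + 1)}. An optional
#' knife-edge selectivity zeroes every bin below the threshold, after which
#' proportions are renormalized. Mass below zero length is clipped by the
#' support (negligible at cv = 0.125).
#'
#' @param model a \code{\link{population_model}}.
#' @param knife_edge optional knife-edge threshold in cm (e.g. 75 for the
#'   Eastern minimum size, 170 for the Western).
#' @param support length support in cm, \code{c(lower, upper)}.
#' @return Object of class \code{size_sampling_distribution}: data frame
#'   with \code{bin_lower}, \code{proportion}, \code{cdf}.
#' @export
expected_size_distribution <- function(model, knife_edge = NULL,
                                       support = c(0, 400)) {
  lowers <- seq(support[1], support[2] - 1)
  weights <- survivorship(model)
  sigma <- model$length_cv * model$mean_length
  prop <- numeric(length(lowers))
  for (a in seq_along(model$ages)) {
    prop <- prop + weights[a] *
      (stats::pnorm(lowers + 1, model$mean_length[a], sigma[a]) -
         stats::pnorm(lowers, model$mean_length[a], sigma[a]))
  }
  if (!is.null(knife_edge)) prop[lowers < knife_edge] <- 0
  if (sum(prop) <= 0) stop_domain("no length support remains after selectivity")
  prop <- prop / sum(prop)
  out <- data.frame(bin_lower = lowers, proportion = prop, cdf = cumsum(prop))
  class(out) <- c("size_sampling_distribution", "data.frame")
  out
}

#' Compare observed sample sizes with the expected distribution
#'
#' Normalizes observed per-bin counts to proportions on the expected
#' distribution's bins and reports both cumulative distributions and their
#' Kolmogorov-Smirnov distance (max absolute CDF difference) as the
#' representativeness measure.
#'
#' @param actual data frame with \code{bin_lower} and \code{count} (1 cm
#'   bins), or a numeric vector of fish lengths (binned internally).
#' @param expected a \code{\link{expected_size_distribution}} result.
#' @return list with the merged per-bin table (\code{bin_lower},
#'   \code{actual}, \code{expected}, \code{actual_cdf}, \code{expected_cdf})
#'   and \code{ks_distance}.
#' @export
compare_sampling <- function(actual, expected) {
  if (is.numeric(actual)) {
    bins <- floor(actual)
    actual <- data.frame(bin_lower = as.numeric(names(table(bins))),
                         count = as.integer(table(bins)))
  }
  total <- sum(actual$count)
  if (total <= 0) stop_domain("zero total actual count")
  cnt <- actual$count[match(expected$bin_lower, actual$bin_lower)]
  cnt[is.na(cnt)] <- 0
  if (sum(cnt) < total)
    warning("some actual counts fall outside the expected support and are dropped")
  p_act <- cnt / sum(cnt)
  tab <- data.frame(bin_lower = expected$bin_lower,
                    actual = p_act, expected = expected$proportion,
                    actual_cdf = cumsum(p_act), expected_cdf = expected$cdf)
  list(table = tab, ks_distance = max(abs(tab$actual_cdf - tab$expected_cdf)))
}

# Stock default parameter sets for the simulator and generator. The study's
# mortality and growth inputs come from stock-assessment files that are not
# published with it; these are the field-standard ICCAT assessment values
# and are user-replaceable defaults, not quantities estimated here.
stock_defaults <- function(stock = c("EAST", "WEST")) {
  stock <- match.arg(stock)
  if (stock == "EAST") {
    list(
      ages = 1:20,
      M = c(0.49, 0.24, 0.24, 0.24, 0.24, 0.20, 0.175, 0.15, 0.125,
            rep(0.10, 11)),
      growth = list(l_inf = 318.85, k = 0.093, t0 = -0.97),
      true_alpha = 3.51e-05, true_beta = 2.8785,
      min_size_cm = 75,
      cv_knots = list(sfl = c(30, 60, 100, 150, 300),
                      cv = c(0.20, 0.20, 0.09, 0.09, 0.125))
    )
  } else {
    list(
      ages = 1:20,
      M = rep(0.14, 20),
      growth = list(l_inf = 314.9, k = 0.089, t0 = -1.13),
      true_alpha = 1.77e-05, true_beta = 3.0013,
      min_size_cm = 170,
      cv_knots = list(sfl = c(53, 120, 160, 200, 300),
                      cv = c(0.13, 0.13, 0.35, 0.35, 0.125))
    )
  }
}

#' Default population model for a stock
#'
#' Convenience constructor with the package's stock default mortality and
#' growth values (ICCAT-assessment-style, user-replaceable).
#' @param stock \code{"EAST"} or \code{"WEST"}.
#' @param ... overrides passed to \code{\link{population_model}}.
#' @export
default_population_model <- function(stock = c("EAST", "WEST"), ...) {
  d <- stock_defaults(match.arg(stock))
  args <- utils::modifyList(
    list(ages = d$ages, M = d$M, growth = d$growth, length_cv = 0.125),
    list(...))
  do.call(population_model, args)
}
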