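# Synthetic fishery-data generator. Emulates the statistical structure the
# downstream analyses assume: two stocks, survivorship-driven age (hence
# size) composition, size-dependent CV of weight at length, minimum-size
# truncation, mixed measurement types across fleets, unbalanced month/area
# coverage, and a seasonal condition cycle injected as monthly offsets to
# the allometric exponent.

#' Fleet configuration for the synthetic fishery
#'
#' One fleet samples one gear in one area over a set of months, retains fish
#' above a knife-edge minimum size (optionally modulated by a selectivity
#' curve) and records a fixed subset of measurement types with per-type
#' additive measurement noise.
#'
#' @param gear gear label (e.g. \code{"BAIT_BOAT"}, \code{"LONGLINE"}).
#' @param area geographic area code (one of the 14 sampling areas).
#' @param months_active subset of 1:12 during which the fleet operates.
#' @param min_size_cm knife-edge retention threshold on true SFL, cm.
#' @param selectivity optional function of SFL returning a retention
#'   probability in [0, 1], applied on top of the knife edge.
#' @param measurement_types which of SFL, CFL, LD1, HeadL, PreopL, RWT, GWT,
#'   GGWT, GGTWT, DWT the fleet records.
#' @param measurement_noise_sd named numeric: additive Normal noise SD per
#'   recorded type (cm or kg); unnamed types get 0.
#' @param share relative share of the simulated catch taken by this fleet.
#' @return An object of class \code{fleet_config}.
#' @export
fleet_config <- function(gear, area, months_active = 1:12, min_size_cm = 0,
                         selectivity = NULL,
                         measurement_types = c("SFL", "RWT"),
                         measurement_noise_sd = numeric(), share = 1) {
  months_active <- as.integer(months_active)
  if (length(months_active) == 0 || !all(months_active %in% 1:12))
    stop_domain("months_active must be a non-empty subset of 1..12")
  if (min_size_cm < 0) stop_domain("min_size_cm must be >= 0")
  if (!area %in% AREA_CODES)
    stop_domain("unknown area code: ", area)
  bad <- setdiff(measurement_types, names(MEASUREMENT_COLUMNS))
  if (length(bad)) stop_domain("unknown measurement types: ",
                               paste(bad, collapse = ", "))
  structure(list(gear = gear, area = area, months_active = months_active,
                 min_size_cm = min_size_cm, selectivity = selectivity,
                 measurement_types = measurement_types,
                 measurement_noise_sd = measurement_noise_sd, share = share),
            class = "fleet_config")
}

#' Default fleet structure for a stock
#'
#' A small set of fleets emulating the unbalanced gear/month/area coverage
#' of real bluefin sampling: commercial fleets bound by the stock's minimum
#' size (75 cm SFL East, 170 cm West) recording different measurement-type
#' mixes, plus a research fleet unconstrained by minimum size that measures
#' several types on the same fish (without such dual measurements no
#' conversion could be fitted from the data).
#'
#' @param stock \code{"EAST"} or \code{"WEST"}.
#' @return list of \code{\link{fleet_config}}.
#' @export
default_fleets <- function(stock = c("EAST", "WEST")) {
  stock <- match.arg(stock)
  if (stock == "EAST") {
    list(
      fleet_config("BAIT_BOAT", "SG", 1:12, 75,
                   measurement_types = c("SFL", "RWT"),
                   measurement_noise_sd = c(SFL = 0.5, RWT = 0.5), share = 0.30),
      fleet_config("PURSE_SEINE", "CM", 5:11, 75,
                   measurement_types = c("CFL", "GGWT"),
                   measurement_noise_sd = c(CFL = 1.0, GGWT = 1.0), share = 0.20),
      fleet_config("LONGLINE", "EM", 1:12, 75,
                   measurement_types = c("CFL", "GWT"),
                   measurement_noise_sd = c(CFL = 1.0, GWT = 0.5), share = 0.15),
      fleet_config("TRAP", "AIMA", 4:10, 75,
                   measurement_types = c("SFL", "GWT"),
                   measurement_noise_sd = c(SFL = 0.5, GWT = 0.5), share = 0.15),
      fleet_config("RESEARCH", "WM", 1:12, 0,
                   measurement_types = c("SFL", "CFL", "RWT", "GWT", "GGWT"),
                   measurement_noise_sd = c(SFL = 0.3, CFL = 0.5, RWT = 0.3,
                                            GWT = 0.3, GGWT = 0.3), share = 0.20)
    )
  } else {
    list(
      fleet_config("ROD_REEL", "MAGESS", 5:11, 170,
                   measurement_types = c("SFL", "RWT"),
                   measurement_noise_sd = c(SFL = 0.5, RWT = 0.5), share = 0.35),
      fleet_config("LONGLINE", "WCA", 1:12, 170,
                   measurement_types = c("CFL", "DWT"),
                   measurement_noise_sd = c(CFL = 1.0, DWT = 1.0), share = 0.30),
      fleet_config("HARPOON", "GSL", 6:11, 170,
                   measurement_types = c("SFL", "DWT"),
                   measurement_noise_sd = c(SFL = 0.5, DWT = 1.0), share = 0.10),
      fleet_config("RESEARCH", "MAB", 1:12, 0,
                   measurement_types = c("SFL", "CFL", "RWT", "DWT"),
                   measurement_noise_sd = c(SFL = 0.3, CFL = 0.5, RWT = 0.3,
                                            DWT = 0.3), share = 0.25)
    )
  }
}

#' Synthetic-population generator configuration
#'
#' Collects everything the generator needs: the true allometric law, the
#' population's age structure and growth, the size-dependent CV of weight
#' at length (the heteroscedasticity the weighted fit is designed for), a
#' 12-month cycle of exponent offsets (the seasonal condition signal,
#' centered to mean zero), and the fleet structure. Defaults follow the
#' stock: published annual weight-length coefficients as the true law,
#' ICCAT-assessment-style mortality and growth (user-replaceable defaults;
#' the study's own inputs are unpublished), 12.5% length CV, and weight-CV
#' knots tracing the observed per-stock CV-at-size patterns.
#'
#' @param stock \code{"EAST"} or \code{"WEST"}.
#' @param n_fish number of latent fish to draw (0 gives an empty dataset).
#' @param seed integer seed; the whole simulation draws from one stream
#'   seeded here, so identical config + seed gives identical output.
#' @param true_alpha,true_beta parameters of the true allometry
#'   \code{RWT = alpha * SFL^beta} (kg, cm).
#' @param ages,M_at_age,growth,length_cv population structure, as in
#'   \code{\link{population_model}}.
#' @param weight_cv_profile list \code{list(sfl=, cv=)} of piecewise-linear
#'   knots for the CV of weight at length.
#' @param monthly_exponent_offsets 12 offsets added to \code{true_beta} by
#'   month of capture; centered to mean zero. Default: the centered monthly
#'   deviations of the published monthly exponents for the stock.
#' @param fleets list of \code{\link{fleet_config}}.
#' @param years calendar years sampled uniformly.
#' @return An object of class \code{generator_config}.
#' @export
generator_config <- function(stock = c("EAST", "WEST"), n_fish = 10000,
                             seed = 1, true_alpha = NULL, true_beta = NULL,
                             ages = NULL, M_at_age = NULL, growth = NULL,
                             length_cv = 0.125, weight_cv_profile = NULL,
                             monthly_exponent_offsets = NULL, fleets = NULL,
                             years = 2005:2012) {
  stock <- match.arg(stock)
  d <- stock_defaults(stock)
  ages <- ages %||% d$ages
  M_at_age <- M_at_age %||% d$M
  if (length(M_at_age) == 1) M_at_age <- rep(M_at_age, length(ages))
  if (any(M_at_age <= 0)) stop_domain("M_at_age must all be positive")
  if (length_cv <= 0 || length_cv >= 0.5)
    stop_domain("length_cv must lie in (0, 0.5)")
  if (is.null(monthly_exponent_offsets)) {
    tab <- bft_monthly_coefficients()
    b <- tab$beta[tab$stock == stock]
    monthly_exponent_offsets <- b - mean(b)
  }
  if (length(monthly_exponent_offsets) != 12)
    stop_domain("monthly_exponent_offsets must have length 12")
  monthly_exponent_offsets <- monthly_exponent_offsets -
    mean(monthly_exponent_offsets)
  structure(
    list(stock = stock, n_fish = as.integer(max(n_fish, 0)),
         seed = as.integer(seed),
         true_alpha = true_alpha %||% d$true_alpha,
         true_beta = true_beta %||% d$true_beta,
         ages = ages, M_at_age = M_at_age,
         growth = growth %||% d$growth, length_cv = length_cv,
         weight_cv_profile = weight_cv_profile %||% d$cv_knots,
         monthly_exponent_offsets = monthly_exponent_offsets,
         fleets = fleets %||% default_fleets(stock),
         years = years),
    class = "generator_config"
  )
}

# CV of weight at length from the config's piecewise-linear knot profile.
weight_cv_at <- function(config, sfl) {
  piecewise_linear(sfl, config$weight_cv_profile$sfl, config$weight_cv_profile$cv)
}

generate_population_impl <- function(config) {
  n <- config$n_fish
  empty <- data.frame(fish_id = integer(), age = integer(), year = integer(),
                      month = integer(), sfl = numeric(), rwt = numeric())
  if (n <= 0) return(empty)
  model <- population_model(config$ages, config$M_at_age, config$growth,
                            length_cv = config$length_cv)
  p_age <- survivorship(model)
  age_idx <- sample.int(length(config$ages), n, replace = TRUE, prob = p_age)
  mu <- model$mean_length[age_idx]
  sfl <- stats::rnorm(n, mu, config$length_cv * mu)
  # truncation at zero: redraw the (practically nonexistent) negatives
  while (any(sfl <= 0)) {
    bad <- sfl <= 0
    sfl[bad] <- stats::rnorm(sum(bad), mu[bad], config$length_cv * mu[bad])
  }
  month <- sample.int(12, n, replace = TRUE)
  year <- config$years[sample.int(length(config$years), n, replace = TRUE)]
  # multiplicative lognormal weight noise: weights stay positive and the
  # realized CV of weight at length matches the profile,
  # sigma = sqrt(log(1 + CV^2))
  cv <- weight_cv_at(config, sfl)
  sigma <- sqrt(log(1 + cv^2))
  beta_m <- config$true_beta + config$monthly_exponent_offsets[month]
  rwt <- config$true_alpha * sfl^beta_m * exp(stats::rnorm(n, 0, sigma))
  data.frame(fish_id = seq_len(n), age = config$ages[age_idx], year = year,
             month = month, sfl = sfl, rwt = rwt)
}

#' Generate the latent fish population
#'
#' Draws \code{n_fish} latent fish: age in proportion to survivorship under
#' the configured mortality, length Normal around mean length-at-age with
#' the configured CV (truncated positive), month/year uniform, and round
#' weight from the true allometry with the month's exponent offset and
#' multiplicative lognormal noise whose log-SD \code{sqrt(log(1 + CV^2))}
#' reproduces the configured CV of weight at length.
#'
#' @param config a \code{\link{generator_config}}.
#' @return data frame of latent fish: \code{fish_id}, \code{age},
#'   \code{year}, \code{month}, \code{sfl}, \code{rwt}.
#' @export
generate_population <- function(config) {
  with_seed(config$seed, generate_population_impl(config))
}

#' Reference conversions used as measurement-process truth
#'
#' The generator turns a latent (SFL, RWT) fish into observed measurement
#' types through deterministic linear conversions plus noise. By default
#' the published conversions serve as that truth, composed so every type is
#' expressed directly in terms of the latent basis (SFL for lengths, RWT
#' for weights).
#'
#' @param stock \code{"EAST"} or \code{"WEST"}.
#' @return named list of \code{\link{linear_conversion}}, one per
#'   observable type.
#' @export
default_truth_conversions <- function(stock = c("EAST", "WEST")) {
  stock <- match.arg(stock)
  identity_conv <- function(type) {
    basis <- if (type %in% LENGTH_TYPES) "SFL" else "RWT"
    linear_conversion(basis, type, 0, 1, 1, 0, 3, c(1, 700), c(1, 700),
                      method = "OLS", stock = stock)
  }
  out <- list(SFL = identity_conv("SFL"), RWT = identity_conv("RWT"))
  if (stock == "EAST") {
    out$CFL <- bft_conversion("EAST", "SFL", "CFL")
    out$LD1 <- bft_conversion("EAST", "SFL", "LD1")
    out$GWT <- bft_conversion("EAST", "RWT", "GWT")
    out$GGWT <- bft_conversion("EAST", "RWT", "GGWT")
  } else {
    out$CFL <- bft_conversion("WEST", "SFL", "CFL")
    out$DWT <- bft_conversion("WEST", "RWT", "DWT")
  }
  out
}

apply_measurement_process_impl <- function(latent, fleet, truth, stock) {
  n <- nrow(latent)
  rec <- data.frame(fish_id = latent$fish_id, stock = rep(stock, n),
                    area = rep(fleet$area, n), gear = rep(fleet$gear, n),
                    year = latent$year, month = latent$month,
                    stringsAsFactors = FALSE)
  for (col in MEASUREMENT_COLUMNS) rec[[col]] <- rep(NA_real_, n)
  for (type in fleet$measurement_types) {
    conv <- truth[[type]]
    if (is.null(conv))
      stop_domain("fleet records type ", type,
                  " but no truth conversion is defined for it")
    basis <- if (type %in% LENGTH_TYPES) latent$sfl else latent$rwt
    value <- predict(conv, basis)
    sd <- fleet$measurement_noise_sd[type]
    sd <- if (is.na(sd) || length(sd) == 0) 0 else unname(sd)
    if (sd > 0) {
      noisy <- value + stats::rnorm(n, 0, sd)
      # a recorded measurement is positive by construction: redraw the
      # rare draws that push a tiny fish below zero
      while (any(noisy <= 0)) {
        bad <- noisy <= 0
        noisy[bad] <- value[bad] + stats::rnorm(sum(bad), 0, sd)
      }
      value <- noisy
    }
    rec[[measurement_column(type)]] <- value
  }
  rec$true_sfl <- latent$sfl
  rec$true_rwt <- latent$rwt
  rec
}

#' Turn latent fish into observed measurement records
#'
#' Applies a fleet's measurement process: each recorded type is a
#' deterministic linear conversion of the latent truth (SFL for lengths,
#' RWT for weights) plus additive Normal noise with the fleet's per-type
#' SD. Latent truth is retained in \code{true_sfl}/\code{true_rwt} for test
#' oracles. Draws from the current RNG stream; seed externally (or use
#' \code{\link{simulate_fishery}}) for reproducibility.
#'
#' @param latent latent fish from \code{\link{generate_population}}.
#' @param fleet a \code{\link{fleet_config}}.
#' @param truth named list of \code{\link{linear_conversion}} per type; by
#'   default the published conversions for \code{stock}.
#' @param stock stock tag stored in the records.
#' @return fish-record data frame (one row per fish, one column per
#'   measurement type, NA where the fleet does not record a type).
#' @export
apply_measurement_process <- function(latent, fleet, truth = NULL,
                                      stock = c("EAST", "WEST")) {
  stock <- match.arg(stock)
  truth <- truth %||% default_truth_conversions(stock)
  apply_measurement_process_impl(latent, fleet, truth, stock)
}

#' Apply a fleet's retention to measured records
#'
#' Removes fish below the fleet's knife-edge minimum size (on true SFL),
#' fish caught outside the fleet's active months and, when the fleet has a
#' selectivity curve, fish failing a Bernoulli retention draw with
#' probability \code{selectivity(SFL)}.
#'
#' @param records fish records carrying \code{true_sfl}.
#' @param fleet a \code{\link{fleet_config}}.
#' @return the retained records.
#' @export
apply_fishery_selection <- function(records, fleet) {
  keep <- records$true_sfl >= fleet$min_size_cm &
    records$month %in% fleet$months_active
  if (!is.null(fleet$selectivity)) {
    p <- pmin(pmax(fleet$selectivity(records$true_sfl), 0), 1)
    keep <- keep & (stats::runif(nrow(records)) < p)
  }
  records[keep, , drop = FALSE]
}

simulate_fishery_impl <- function(config, truth) {
  latent <- generate_population_impl(config)
  if (nrow(latent) == 0) {
    rec <- apply_measurement_process_impl(latent, config$fleets[[1]], truth,
                                          config$stock)
    return(rec)
  }
  shares <- vapply(config$fleets, function(f) f$share, 0)
  assign <- sample.int(length(config$fleets), nrow(latent), replace = TRUE,
                       prob = shares / sum(shares))
  pieces <- vector("list", length(config$fleets))
  for (i in seq_along(config$fleets)) {
    sub <- latent[assign == i, , drop = FALSE]
    rec <- apply_measurement_process_impl(sub, config$fleets[[i]], truth,
                                          config$stock)
    pieces[[i]] <- apply_fishery_selection(rec, config$fleets[[i]])
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$fish_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic fishery dataset
#'
#' Runs the full generator under one seeded stream: latent population,
#' fleet assignment by share, measurement process, then fleet retention
#' (knife edge, months, selectivity). Because retention discards fish, the
#' returned record count is smaller than \code{n_fish}; pass
#' \code{target_records} to over-generate internally and truncate to an
#' exact record count (deterministic under the seed).
#'
#' @param config a \code{\link{generator_config}}.
#' @param truth optional truth conversions (default: published tables).
#' @param target_records if given, exactly this many records are returned
#'   (the latent population is inflated accordingly; an error is raised if
#'   retention is too severe for the inflation factor).
#' @param inflation over-generation factor used with \code{target_records}.
#' @return fish-record data frame.
#' @export
simulate_fishery <- function(config, truth = NULL, target_records = NULL,
                             inflation = 3) {
  truth <- truth %||% default_truth_conversions(config$stock)
  if (!is.null(target_records)) {
    config$n_fish <- as.integer(ceiling(target_records * inflation))
    out <- with_seed(config$seed, simulate_fishery_impl(config, truth))
    if (nrow(out) < target_records)
      stop_domain("retention kept only ", nrow(out), " of the requested ",
                  target_records, " records; raise inflation")
    out <- out[seq_len(target_records), , drop = FALSE]
    return(out)
  }
  with_seed(config$seed, simulate_fishery_impl(config, truth))
}

#' Write / read fish records as CSV
#'
#' One row per fish; empty fields are missing measurements. Latent-truth
#' columns are written to a companion file when requested.
#'
#' @param records fish-record data frame.
#' @param path output CSV path.
#' @param latent_path optional path for a companion CSV holding
#'   \code{fish_id}, \code{true_sfl}, \code{true_rwt}.
#' @export
write_records_csv <- function(records, path, latent_path = NULL) {
  public <- records[, c("fish_id", "stock", "area", "gear", "year", "month",
                        unname(MEASUREMENT_COLUMNS))]
  utils::write.csv(public, path, row.names = FALSE, na = "")
  if (!is.null(latent_path) && all(c("true_sfl", "true_rwt") %in% names(records)))
    utils::write.csv(records[, c("fish_id", "true_sfl", "true_rwt")],
                     latent_path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path, latent_path = NULL) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(latent_path)) {
    lat <- utils::read.csv(latent_path, stringsAsFactors = FALSE)
    rec <- merge(rec, lat, by = "fish_id", sort = TRUE)
  }
  rec
}
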