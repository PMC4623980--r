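# End-to-end workflow: simulate (or load) -> fit conversions ->
# standardize -> bin CVs -> annual fits -> quantile/bootstrap sensitivity ->
# sampling representativeness -> condition model -> monthly table.

#' Pipeline configuration
#'
#' @param stock \code{"EAST"} or \code{"WEST"}.
#' @param generator a \code{\link{generator_config}} (or list of arguments
#'   for one); ignored when \code{input_csv} is given.
#' @param input_csv optional path to a fish-record CSV to analyze instead
#'   of simulating.
#' @param seed master seed; every stochastic stage derives its stream from
#'   it.
#' @param gate r-square threshold for standardization conversions.
#' @param weighting \code{"INV_CV"} or \code{"NONE"} for the headline fit.
#' @param taus quantile levels for the quantile-regression sensitivity.
#' @param bootstrap_B bootstrap replicates per scheme.
#' @param bootstrap_schemes which resampling schemes to run.
#' @param condition_factors fixed factors requested for the condition
#'   model; factors without 2 observed levels are dropped with a message.
#' @param out_dir optional directory for CSV/JSON outputs.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(stock = "EAST", generator = NULL,
                            input_csv = NULL, seed = 1, gate = 0.98,
                            weighting = "INV_CV",
                            taus = c(0.025, 0.25, 0.5, 0.75, 0.975),
                            bootstrap_B = 1000,
                            bootstrap_schemes = c("EQUAL_PROB", "UNIFORM_PER_BIN"),
                            condition_factors = c("month", "maturity", "area_group"),
                            out_dir = NULL) {
  stopifnot(bootstrap_B >= 1, all(taus > 0 & taus < 1))
  if (is.null(generator) && is.null(input_csv))
    generator <- generator_config(stock = stock, seed = seed)
  if (is.list(generator) && !inherits(generator, "generator_config"))
    generator <- do.call(generator_config, generator)
  structure(list(stock = stock, generator = generator, input_csv = input_csv,
                 seed = as.integer(seed), gate = gate, weighting = weighting,
                 taus = taus, bootstrap_B = as.integer(bootstrap_B),
                 bootstrap_schemes = bootstrap_schemes,
                 condition_factors = condition_factors, out_dir = out_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with fields matching the \code{pipeline_config}
#'   arguments (the \code{generator} entry is a nested mapping of
#'   \code{\link{generator_config}} arguments).
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

config_hash <- function(config) {
  slim <- config[setdiff(names(config), "out_dir")]
  slim$generator <- if (!is.null(slim$generator))
    slim$generator[setdiff(names(slim$generator), "fleets")]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(slim, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

fit_as_list <- function(fit) {
  list(alpha = fit$alpha, beta = fit$beta, weighting = fit$weighting,
       n = fit$n, residual_se = fit$residual_se, aic = fit$aic,
       rmse = fit$rmse, converged = fit$converged,
       iterations = fit$iterations)
}

#' Run the full biometrics workflow
#'
#' Executes every stage on one stock's data and returns a result bundle;
#' any stage failure halts with a stage-labelled error. The JSON report
#' contains only reproducible quantities (parameters, diagnostics, seeds
#' and a configuration hash, no timestamps), so two runs of the same
#' configuration produce byte-identical reports.
#'
#' @param config a \code{\link{pipeline_config}} (or YAML path).
#' @return invisible list: \code{records}, \code{conversions},
#'   \code{standardized}, \code{cv_profile}, \code{fit_weighted},
#'   \code{fit_unweighted}, \code{quantile_fits}, \code{bootstraps},
#'   \code{sampling}, \code{condition}, \code{monthly}, \code{report}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
  }

  records <- stage("data", {
    if (!is.null(config$input_csv)) {
      rec <- read_records_csv(config$input_csv)
      need <- c("fish_id", "stock", "area", "gear", "year", "month")
      missing_cols <- setdiff(need, names(rec))
      if (length(missing_cols))
        stop("input is missing required columns: ",
             paste(missing_cols, collapse = ", "))
      rec
    } else {
      simulate_fishery(config$generator)
    }
  })

  conversions <- stage("conversions", fit_stock_conversions(records, config$stock))

  standardized <- stage("standardize", {
    std <- standardize_records(records, conversions, gate = config$gate)
    if (nrow(wlr_input(std)) < 10)
      stop("no usable standardized length-weight pairs: every needed ",
           "conversion was refused by the r2 gate (", config$gate,
           ") and too few records carry direct SFL and RWT")
    std
  })
  wlr_in <- wlr_input(standardized)

  cv_profile <- stage("bin_cv", bin_cv_profile(wlr_in))
  fit_w <- stage("fit_wlr", fit_power_law(wlr_in$sfl_std, wlr_in$rwt_std,
                                          weighting = "INV_CV",
                                          cv_profile = cv_profile))
  fit_u <- stage("fit_wlr", fit_power_law(wlr_in$sfl_std, wlr_in$rwt_std,
                                          weighting = "NONE"))
  fit_main <- if (config$weighting == "INV_CV") fit_w else fit_u

  quantile_fits <- stage("quantile", lapply(config$taus, function(tau)
    fit_power_quantile(wlr_in$sfl_std, wlr_in$rwt_std, tau = tau,
                       start = fit_main)))
  names(quantile_fits) <- paste0("tau_", config$taus)

  bootstraps <- stage("bootstrap", {
    out <- list()
    for (i in seq_along(config$bootstrap_schemes)) {
      sch <- config$bootstrap_schemes[i]
      out[[sch]] <- bootstrap_wlr(wlr_in$sfl_std, wlr_in$rwt_std,
                                  scheme = sch, B = config$bootstrap_B,
                                  seed = config$seed + 1000L + i,
                                  weighting = config$weighting)
    }
    out
  })

  sampling <- stage("popsim", {
    model <- default_population_model(config$stock)
    expected <- expected_size_distribution(
      model, knife_edge = stock_defaults(config$stock)$min_size_cm)
    c(list(expected = expected), compare_sampling(wlr_in$sfl_std, expected))
  })

  condition <- stage("condition", {
    resid <- scaled_residuals(standardized, fit_main)
    usable <- vapply(config$condition_factors, function(f)
      length(unique(resid[[f]][!resid$excluded])) >= 2, TRUE)
    if (any(!usable))
      message("dropping single-level condition factors: ",
              paste(config$condition_factors[!usable], collapse = ", "))
    fit_condition_model(resid, factors = config$condition_factors[usable])
  })
  lsm <- stage("condition", lsmeans_month(condition))
  monthly <- stage("monthly_table",
                   monthly_wlr_table(fit_main, lsm, condition$mse))

  report <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    stock = config$stock,
    n_records = nrow(records),
    n_standardized = nrow(wlr_in),
    conversions = lapply(conversions, function(cv)
      cv[c("x_type", "y_type", "alpha", "beta", "r2", "residual_se", "n")]),
    annual_fit_weighted = fit_as_list(fit_w),
    annual_fit_unweighted = fit_as_list(fit_u),
    quantile_fits = lapply(quantile_fits, function(q)
      q[c("tau", "alpha", "beta", "pinball_loss")]),
    bootstrap = lapply(bootstraps, function(b)
      list(scheme = b$scheme, B = b$B, seed = b$seed,
           summary = lapply(b$summary, as.list))),
    sampling_ks_distance = sampling$ks_distance,
    condition_mse = condition$mse,
    lsmeans_month = lsm,
    monthly_beta = monthly$beta_by_month,
    monthly_alpha = monthly$alpha
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    utils::write.csv(standardized,
                     file.path(config$out_dir, "standardized.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(data.frame(month = 1:12, alpha = monthly$alpha,
                                beta = monthly$beta_by_month),
                     file.path(config$out_dir, "monthly_wlr.csv"),
                     row.names = FALSE)
  }

  invisible(list(records = records, conversions = conversions,
                 standardized = standardized, cv_profile = cv_profile,
                 fit_weighted = fit_w, fit_unweighted = fit_u,
                 quantile_fits = quantile_fits, bootstraps = bootstraps,
                 sampling = sampling, condition = condition,
                 lsmeans = lsm, monthly = monthly, report = report))
}
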