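#' Published biometric coefficient tables
#'
#' The package ships the published Atlantic bluefin tuna coefficient tables
#' (stored verbatim as JSON under \code{inst/extdata}): per-stock linear
#' length-length and weight-weight conversions, per-stock annual
#' weight-length power laws, and the monthly weight-length coefficients.
#' These let deterministic quantities (predicted weights, stock
#' differences, conversion-factor divergences) be computed without any raw
#' data, and provide the reference conversions used by the synthetic-data
#' generator.
#'
#' @param stock \code{"EAST"} or \code{"WEST"} (case-insensitive).
#' @return \code{bft_coefficients}: a list with data frames \code{linear}
#'   and \code{power} plus the stock tag.
#' @export
bft_coefficients <- function(stock = c("EAST", "WEST")) {
  stock <- match.arg(toupper(stock), c("EAST", "WEST"))
  file <- system.file("extdata",
                      paste0("coefficients_", tolower(stock), ".json"),
                      package = "bftbiom", mustWork = TRUE)
  raw <- jsonlite::fromJSON(file)
  list(stock = stock, linear = raw$linear, power = raw$power)
}

#' @rdname bft_coefficients
#' @param x_type,y_type measurement types selecting one linear conversion
#'   row (e.g. \code{"CFL"} to \code{"SFL"}).
#' @return \code{bft_conversion}: the selected row as a
#'   \code{\link{linear_conversion}}.
#' @export
bft_conversion <- function(stock, x_type, y_type) {
  tab <- bft_coefficients(stock)
  row <- tab$linear[tab$linear$x_type == x_type & tab$linear$y_type == y_type, ]
  if (nrow(row) != 1)
    stop_domain("no published ", x_type, "->", y_type,
                " conversion for the ", tab$stock, " stock")
  linear_conversion(
    x_type = x_type, y_type = y_type, alpha = row$alpha, beta = row$beta,
    r2 = row$r2, residual_se = row$residual_se, n = row$n,
    x_range = c(row$x_min, row$x_max), y_range = c(row$y_min, row$y_max),
    method = "ROBUST", stock = tab$stock
  )
}

#' @rdname bft_coefficients
#' @return \code{bft_standard_conversions}: the list of published
#'   conversions used for standardization of the given stock (those whose
#'   r-square clears the 0.98 gate are the only ones
#'   \code{\link{standardize_records}} will apply).
#' @export
bft_standard_conversions <- function(stock) {
  pairs <- if (toupper(stock) == "WEST") {
    list(c("CFL", "SFL"), c("DWT", "RWT"))
  } else {
    list(c("CFL", "SFL"), c("GWT", "RWT"), c("GGWT", "RWT"))
  }
  out <- lapply(pairs, function(p) bft_conversion(stock, p[1], p[2]))
  names(out) <- vapply(pairs, function(p) paste0(p[1], "->", p[2]), "")
  out
}

#' @rdname bft_coefficients
#' @return \code{bft_annual_wlr}: the stock's published annual standardized
#'   weight-length relationship (CV-weighted fit) as a
#'   \code{\link{power_law_fit}}.
#' @export
bft_annual_wlr <- function(stock) {
  tab <- bft_coefficients(stock)
  row <- tab$power[tab$power$standardized, ][1, ]
  power_law_fit(alpha = row$alpha, beta = row$beta, weighting = "INV_CV",
                n = row$n, residual_se = row$residual_se, stock = tab$stock)
}

#' @rdname bft_coefficients
#' @return \code{bft_monthly_coefficients}: data frame with columns
#'   \code{month} (1-12), \code{stock}, \code{alpha}, \code{beta} holding
#'   the published monthly weight-length coefficients for both stocks.
#' @export
bft_monthly_coefficients <- function() {
  file <- system.file("extdata", "monthly_coefficients.json",
                      package = "bftbiom", mustWork = TRUE)
  raw <- jsonlite::fromJSON(file)
  rbind(
    data.frame(month = 1:12, stock = "EAST",
               alpha = raw$east$alpha, beta = raw$east$beta),
    data.frame(month = 1:12, stock = "WEST",
               alpha = raw$west$alpha, beta = raw$west$beta)
  )
}

#' @rdname bft_coefficients
#' @return \code{bft_monthly_wlr}: the published monthly coefficients of
#'   one stock as a \code{\link{monthly_wlr}} object usable with
#'   \code{\link{predict_monthly_weight}}.
#' @export
bft_monthly_wlr <- function(stock = c("EAST", "WEST")) {
  stock <- match.arg(toupper(stock), c("EAST", "WEST"))
  tab <- bft_monthly_coefficients()
  tab <- tab[tab$stock == stock, ]
  monthly_wlr(alpha = tab$alpha[1], beta_by_month = tab$beta, stock = stock)
}
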