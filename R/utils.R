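# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generator calls are reproducible
#' without clobbering the caller's stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Piecewise-linear interpolation through (x, y) knots, flat extrapolation.
piecewise_linear <- function(x, knots_x, knots_y) {
  stopifnot(length(knots_x) == length(knots_y), !is.unsorted(knots_x))
  stats::approx(knots_x, knots_y, xout = x, rule = 2)$y
}

# Moment coefficient of skewness (biased, the descriptive form).
skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

# Coefficient of variation.
cv_of <- function(x) stats::sd(x) / mean(x)

stop_domain <- function(...) stop(..., call. = FALSE)

# Measurement-type vocabulary and the CSV columns that carry each type.
LENGTH_TYPES <- c("SFL", "CFL", "LD1", "HeadL", "PreopL")
WEIGHT_TYPES <- c("RWT", "GWT", "GGWT", "GGTWT", "DWT")
MEASUREMENT_COLUMNS <- c(
  SFL = "sfl_cm", CFL = "cfl_cm", LD1 = "ld1_cm",
  HeadL = "headl_cm", PreopL = "preopl_cm",
  RWT = "rwt_kg", GWT = "gwt_kg", GGWT = "ggwt_kg",
  GGTWT = "ggtwt_kg", DWT = "dwt_kg"
)

measurement_column <- function(type) {
  col <- MEASUREMENT_COLUMNS[[match.arg(type, names(MEASUREMENT_COLUMNS))]]
  col
}

# Area codes and their grouping for the condition analysis. SG fishes the
# approaches to the Mediterranean and is grouped with the west-central
# Mediterranean.
AREA_CODES <- c("GOM", "SABFEC", "MAB", "MAGESS", "GSL", "WCA", "ECA",
                "BB", "AIMA", "SG", "WM", "CM", "EM", "WATL")
AREA_GROUPS <- c(
  GOM = "WEST_ATLANTIC", SABFEC = "WEST_ATLANTIC", MAB = "WEST_ATLANTIC",
  MAGESS = "WEST_ATLANTIC", GSL = "WEST_ATLANTIC", WCA = "WEST_ATLANTIC",
  WATL = "WEST_ATLANTIC",
  ECA = "EAST_ATLANTIC", BB = "EAST_ATLANTIC", AIMA = "EAST_ATLANTIC",
  SG = "WC_MED", WM = "WC_MED", CM = "WC_MED",
  EM = "E_MED"
)
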