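#' Read a daily sea-ice concentration series
#'
#' @param x CSV path or data.frame with columns `date` (ISO) and
#'   `concentration` (fraction of ice cover in \[0, 1\] for the core
#'   wintering area, already aggregated over its four 25-km grid cells).
#' @return A data.frame with `date` (Date) and `concentration`, sorted by
#'   date.
#' @export
read_ice_series <- function(x) {
  df <- if (is.character(x)) utils::read.csv(x) else as.data.frame(x)
  if (!all(c("date", "concentration") %in% names(df)))
    stop("ice series must have columns date, concentration")
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("unparseable dates in ice series")
  if (any(!is.finite(df$concentration)) ||
      any(df$concentration < 0 | df$concentration > 1))
    stop("concentrations must lie in [0, 1]")
  df <- df[order(df$date), , drop = FALSE]
  if (anyDuplicated(df$date)) stop("duplicated dates in ice series")
  rownames(df) <- NULL
  df
}

winter_window <- function(winter) {
  seq(as.Date(sprintf("%d-11-01", winter - 1)),
      as.Date(sprintf("%d-04-30", winter)), by = "day")
}

winter_slice <- function(series, winter) {
  window <- winter_window(winter)
  idx <- match(window, series$date)
  if (anyNA(idx))
    stop("ice series is missing ", sum(is.na(idx)), " day(s) in winter ",
         winter, ": ", paste(utils::head(window[is.na(idx)], 5), collapse = ", "),
         if (sum(is.na(idx)) > 5) ", ..." else "")
  series$concentration[idx]
}

#' Count extreme ice days in a wintering period
#'
#' Number of days in the November 1 - April 30 wintering window with ice
#' concentration at or above the extreme-ice threshold over the core
#' wintering area.  The window must be fully covered; gaps raise an error
#' (no silent imputation).
#'
#' @param series Daily series from [read_ice_series()].
#' @param winter The calendar year in which the winter ends (the window is
#'   Nov 1 of `winter - 1` through Apr 30 of `winter`).
#' @param threshold Extreme-ice concentration threshold (default 0.95,
#'   boundary included).
#' @return Integer count of extreme ice days (window length 181, or 182
#'   when February of `winter` has 29 days).
#' @export
ice_days <- function(series, winter, threshold = 0.95) {
  sum(winter_slice(series, winter) >= threshold)
}

#' Count extreme low-ice days in a wintering period
#'
#' Companion metric to [ice_days()]: days with concentration strictly
#' below the low-ice threshold (default 0.15).  On the observed series the
#' two counts are strongly negatively correlated, which is why only
#' `ice_days` enters the fitted model.
#'
#' @inheritParams ice_days
#' @param threshold Low-ice threshold (default 0.15, exclusive).
#' @export
low_ice_days <- function(series, winter, threshold = 0.15) {
  sum(winter_slice(series, winter) < threshold)
}

#' z-standardize a covariate series
#'
#' Centers and scales to sample mean 0, sample SD 1 (n - 1 denominator)
#' over the unmasked entries; masked entries are set to 0 (the mean), so
#' a masked year contributes nothing to a centered linear predictor.
#'
#' @param x Numeric series.
#' @param mask Logical vector (or indices) marking entries excluded from
#'   the standardization (e.g. the 2001 sensitivity refit).
#' @return Standardized series, same length as `x`.
#' @export
zstandardize <- function(x, mask = NULL) {
  keep <- rep(TRUE, length(x))
  if (!is.null(mask)) {
    if (is.logical(mask)) keep <- !mask else keep[mask] <- FALSE
  }
  v <- x[keep]
  if (length(v) < 2) stop("need at least two unmasked values")
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stop("zero standard deviation; cannot standardize")
  z <- (x - mean(v)) / s
  z[!keep] <- 0
  z
}

#' Logit-scale linear predictor for adult survival
#'
#' `mu + beta_lin * x + beta_quad * x^2 + eps`: a quadratic response of
#' adult survival to standardized extreme-ice days, so that with
#' `beta_quad < 0` survival peaks at intermediate ice conditions.
#'
#' @param mu Mean logit survival.
#' @param eps Annual random effect(s) on the logit scale.
#' @param x Standardized ice-days covariate.
#' @param beta_lin,beta_quad Linear and quadratic coefficients.
#' @param prob If `TRUE`, return the inverse-logit (probability scale).
#' @return Logit (or probability) of adult survival, vectorized.
#' @export
linear_predictor_phiA <- function(mu, eps, x, beta_lin, beta_quad, prob = FALSE) {
  eta <- mu + beta_lin * x + beta_quad * x^2 + eps
  if (prob) stats::plogis(eta) else eta
}

#' Logit-scale linear predictor for nest success
#'
#' Quadratic ice-days response plus linear breeding-ground terms for fox
#' presence and summer precipitation.
#'
#' @inheritParams linear_predictor_phiA
#' @param ice Standardized ice-days covariate (winter ending in the
#'   breeding year).
#' @param fox,precip Standardized fox-sign and June-August precipitation
#'   covariates.
#' @param beta_fox,beta_precip Their coefficients.
#' @export
linear_predictor_ns <- function(mu, eps, ice, fox, precip,
                                beta_lin, beta_quad, beta_fox, beta_precip,
                                prob = FALSE) {
  eta <- mu + beta_lin * ice + beta_quad * ice^2 +
    beta_fox * fox + beta_precip * precip + eps
  if (prob) stats::plogis(eta) else eta
}

#' Logit-scale linear predictor for first-year survival
#'
#' Linear response to the winter Arctic Oscillation index, a proxy for
#' region-wide conditions experienced by first-year birds.
#'
#' @inheritParams linear_predictor_phiA
#' @param ao Standardized Arctic Oscillation index.
#' @param beta Its coefficient.
#' @export
linear_predictor_phiJ <- function(mu, eps, ao, beta, prob = FALSE) {
  eta <- mu + beta * ao + eps
  if (prob) stats::plogis(eta) else eta
}

#' Assemble standardized annual covariates
#'
#' Computes extreme-ice-day counts from the daily series for the winters
#' ending in `years`, joins the annual indices, and z-standardizes every
#' column.  Masked years (e.g. 2001 for the sensitivity refit) are
#' excluded from the standardization and their standardized values set to
#' 0, so they contribute the mean to every linear predictor.
#'
#' @param ice_series Daily series from [read_ice_series()].
#' @param annual CSV path or data.frame with columns `year`, `ao`, `fox`,
#'   `precip` (raw scales).
#' @param years Study years (winters ending in these years must be fully
#'   covered by `ice_series`).
#' @param mask_years Calendar years excluded from standardization.
#' @param threshold Extreme-ice threshold passed to [ice_days()].
#' @return A data.frame: `year`, `ice_days_raw`, `ice_days` (standardized),
#'   `ao`, `fox`, `precip` (standardized), `masked`.
#' @export
build_annual_covariates <- function(ice_series, annual, years,
                                    mask_years = integer(0), threshold = 0.95) {
  ann <- if (is.character(annual)) utils::read.csv(annual) else as.data.frame(annual)
  if (!all(c("year", "ao", "fox", "precip") %in% names(ann)))
    stop("annual covariate table must have columns year, ao, fox, precip")
  idx <- match(years, ann$year)
  if (anyNA(idx)) stop("annual covariates missing for years: ",
                       paste(years[is.na(idx)], collapse = ", "))
  raw <- vapply(years, function(y) ice_days(ice_series, y, threshold), numeric(1))
  mask <- years %in% mask_years
  data.frame(
    year = years,
    ice_days_raw = raw,
    ice_days = zstandardize(raw, mask),
    ao = zstandardize(ann$ao[idx], mask),
    fox = zstandardize(ann$fox[idx], mask),
    precip = zstandardize(ann$precip[idx], mask),
    masked = mask
  )
}
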