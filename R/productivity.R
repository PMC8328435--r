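#' Read annual nest records
#'
#' @param x CSV path or data.frame with columns `year`, `n_nests`,
#'   `n_success`, and `clutch_sizes` (semicolon-separated clutch-at-hatch
#'   counts for the successful nests; empty when none).
#' @return A data.frame with a `clutches` list-column of integer vectors.
#' @export
read_nest_data <- function(x) {
  df <- if (is.character(x)) utils::read.csv(x, colClasses = c(clutch_sizes = "character")) else as.data.frame(x)
  req <- c("year", "n_nests", "n_success")
  if (!all(req %in% names(df)))
    stop("nest table must have columns year, n_nests, n_success, clutch_sizes")
  bad <- df$n_success > df$n_nests | df$n_success < 0 | df$n_nests < 0
  if (any(bad))
    stop("row ", which(bad)[1], ": n_success must lie in [0, n_nests]")
  cl <- if ("clutch_sizes" %in% names(df)) as.character(df$clutch_sizes) else character(nrow(df))
  df$clutches <- lapply(cl, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(integer(0))
    v <- as.numeric(strsplit(s, ";")[[1]])
    if (any(is.na(v)) || any(v < 0) || any(v != round(v)))
      stop("clutch sizes must be non-negative integers")
    as.integer(v)
  })
  df$clutch_sizes <- NULL
  df
}

#' Binomial log-likelihood of annual nest success
#'
#' `sum_t log Binomial(n_success_t | n_nests_t, ns_t)`, the likelihood of
#' the number of nests with at least one hatched egg each year.
#'
#' @param data Nest data from [read_nest_data()] (columns `n_nests`,
#'   `n_success`).
#' @param ns Annual nest-success probabilities, length `nrow(data)` (a
#'   scalar is recycled).
#' @return Log-likelihood.
#' @export
nest_success_loglik <- function(data, ns) {
  if (any(data$n_success > data$n_nests))
    stop("n_success exceeds n_nests")
  ns <- rep_len(ns, nrow(data))
  check_prob(ns)
  sum(stats::dbinom(data$n_success, data$n_nests, ns, log = TRUE))
}

#' Poisson log-likelihood of clutch sizes at hatch
#'
#' Each observed clutch (successful nests only) is Poisson with mean `cs`,
#' the time-constant average clutch size.
#'
#' @param data Nest data from [read_nest_data()] (list-column `clutches`),
#'   or a plain vector of clutch sizes.
#' @param cs Mean clutch size (> 0).
#' @return Log-likelihood (0 for no observed clutches).
#' @export
clutch_loglik <- function(data, cs) {
  if (!is.finite(cs) || cs <= 0) stop("cs must be positive")
  k <- if (is.data.frame(data)) unlist(data$clutches) else as.numeric(data)
  if (length(k) == 0) return(0)
  if (any(k < 0)) stop("clutch sizes must be non-negative")
  sum(stats::dpois(k, cs, log = TRUE))
}

#' Fecundity from productivity components
#'
#' Expected ducklings surviving to 30 days per breeding female:
#' `fec_t = ns_t * cs * ds`, the product of nest success, clutch size at
#' hatch, and the fixed 0-to-30-day duckling survival.
#'
#' @param ns Nest-success probability (vectorized over years).
#' @param cs Mean clutch size at hatch.
#' @param ds Duckling survival constant (default 0.67, supplied as data,
#'   not estimated).
#' @return Fecundity, same length as `ns`.
#' @examples
#' fecundity(0.778, 4.297)  # ~2.24 ducklings per breeding female
#' @export
fecundity <- function(ns, cs, ds = 0.67) {
  check_prob(ns)
  if (any(!is.finite(c(cs, ds))) || cs < 0 || ds < 0 || ds > 1)
    stop("cs must be >= 0 and ds in [0, 1]")
  ns * cs * ds
}
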