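#' Stage vector for the four-stage female life cycle
#'
#' Abundance of females in the four stages of the prebreeding-census life
#' cycle: 1-year-olds (`n1`), non-breeding 2-year-olds (`n2`), breeding
#' 2-year-olds (`n3`), and birds aged 3+ (`n4`, all assumed to breed).
#'
#' @param n1,n2,n3,n4 Non-negative stage abundances.
#' @param year Calendar year of the prebreeding census.
#' @return An object of class `stage_vector`: a named numeric vector of
#'   length 4 with a `year` attribute.
#' @examples
#' sv <- stage_vector(100, 50, 25, 500, year = 1992)
#' total_females(sv)
#' breeding_abundance(sv)
#' @export
stage_vector <- function(n1, n2, n3, n4, year = NA_integer_) {
  x <- c(n1 = n1, n2 = n2, n3 = n3, n4 = n4)
  if (any(!is.finite(x)) || any(x < 0))
    stop("stage abundances must be finite and non-negative")
  structure(x, year = year, class = "stage_vector")
}

#' @export
print.stage_vector <- function(x, ...) {
  cat("Stage vector", if (!is.na(attr(x, "year"))) paste0("(year ", attr(x, "year"), ")"), "\n")
  print(unclass(x))
  invisible(x)
}

#' Demographic rates for one projection interval
#'
#' @param phi_j First-year survival (30 days old to age 1), in \[0, 1\].
#' @param phi_a Survival of females aged 1+, in \[0, 1\].
#' @param alpha Breeding probability of 2-year-old females, in \[0, 1\].
#' @param fec Fecundity: expected ducklings (both sexes) surviving to 30
#'   days per breeding female; halved inside the projection because only
#'   females are tracked.
#' @return An object of class `demographic_rates`.
#' @seealso [fecundity()] for building `fec` from nest success, clutch
#'   size, and duckling survival.
#' @export
demographic_rates <- function(phi_j, phi_a, alpha, fec) {
  probs <- c(phi_j = phi_j, phi_a = phi_a, alpha = alpha)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("phi_j, phi_a and alpha must lie in [0, 1]")
  if (!is.finite(fec) || fec < 0) stop("fec must be non-negative")
  structure(list(phi_j = phi_j, phi_a = phi_a, alpha = alpha, fec = fec),
            class = "demographic_rates")
}

as_rates <- function(rates) {
  if (inherits(rates, "demographic_rates")) return(rates)
  do.call(demographic_rates, as.list(rates)[c("phi_j", "phi_a", "alpha", "fec")])
}

#' Stage-structured projection matrix
#'
#' Builds the 4x4 female-only projection matrix for a prebreeding census.
#' Recruitment enters stage 1 from the two breeding stages at rate
#' `(fec / 2) * phi_j`; 1-year-olds move to non-breeding or breeding
#' 2-year-olds at `phi_a * (1 - alpha)` and `phi_a * alpha`; all older
#' stages survive into stage 4 at `phi_a`.
#'
#' @param rates A [demographic_rates()] object (or coercible list).
#' @return A 4x4 non-negative matrix with 6 structurally non-zero entries.
#' @examples
#' projection_matrix(demographic_rates(0.29, 0.878, 0.359, 2.24))
#' @export
projection_matrix <- function(rates) {
  r <- as_rates(rates)
  A <- matrix(0, 4, 4, dimnames = list(paste0("n", 1:4), paste0("n", 1:4)))
  A[1, 3] <- A[1, 4] <- (r$fec / 2) * r$phi_j
  A[2, 1] <- r$phi_a * (1 - r$alpha)
  A[3, 1] <- r$phi_a * r$alpha
  A[4, 2] <- A[4, 3] <- A[4, 4] <- r$phi_a
  A
}

#' Deterministic one-year projection
#'
#' @param sv A [stage_vector()].
#' @param rates A [demographic_rates()] object.
#' @return The projected `stage_vector` (year incremented by one).
#' @export
project_deterministic <- function(sv, rates) {
  stopifnot(inherits(sv, "stage_vector"))
  v <- drop(projection_matrix(rates) %*% as.numeric(sv))
  stage_vector(v[1], v[2], v[3], v[4],
               year = attr(sv, "year") + if (is.na(attr(sv, "year"))) NA else 1L)
}

#' Stochastic one-year projection
#'
#' Demographic-stochasticity counterpart of [project_deterministic()]:
#' recruitment is Poisson, survival of 1-year-olds is split trinomially
#' between the two 2-year-old stages, and survival of stages 2-4 into
#' stage 4 is binomial.  The expectation equals the deterministic
#' projection.  Randomness comes from the R session RNG; call
#' `set.seed()` for reproducibility.
#'
#' @inheritParams project_deterministic
#' @return An integer-valued `stage_vector`.
#' @export
project_stochastic <- function(sv, rates) {
  stopifnot(inherits(sv, "stage_vector"))
  n <- as.numeric(sv)
  if (any(n != round(n)))
    stop("stochastic projection requires integer stage abundances")
  r <- as_rates(rates)
  n1 <- stats::rpois(1, (r$fec / 2) * r$phi_j * (n[3] + n[4]))
  surv1 <- stats::rbinom(1, n[1], r$phi_a)
  n3 <- stats::rbinom(1, surv1, r$alpha)
  n2 <- surv1 - n3
  n4 <- stats::rbinom(1, n[2] + n[3] + n[4], r$phi_a)
  stage_vector(n1, n2, n3, n4,
               year = attr(sv, "year") + if (is.na(attr(sv, "year"))) NA else 1L)
}

#' Total female abundance
#' @param sv A [stage_vector()].
#' @return `n1 + n2 + n3 + n4`.
#' @export
total_females <- function(sv) sum(as.numeric(sv))

#' Breeding abundance (males and females)
#'
#' Breeding stages doubled under an equal sex ratio, matching the quantity
#' estimated by aerial surveys.
#' @param sv A [stage_vector()].
#' @return `(n3 + n4) * 2`.
#' @export
breeding_abundance <- function(sv) {
  n <- as.numeric(sv)
  (n[3] + n[4]) * 2
}

#' Annual population growth rates
#'
#' @param N Positive abundance series (length >= 2).
#' @return `N[t + 1] / N[t]`, one element shorter than the input.
#' @export
lambda_series <- function(N) {
  N <- as.numeric(N)
  if (length(N) < 2) stop("need at least two abundances")
  if (any(!is.finite(N)) || any(N <= 0)) stop("abundances must be positive")
  N[-1] / N[-length(N)]
}

#' Geometric mean growth rate
#'
#' @param lambdas Positive per-interval growth rates.
#' @return `exp(mean(log(lambdas)))`.
#' @export
geometric_mean_growth <- function(lambdas) {
  lambdas <- as.numeric(lambdas)
  if (any(!is.finite(lambdas)) || any(lambdas <= 0))
    stop("growth rates must be positive")
  exp(mean(log(lambdas)))
}
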