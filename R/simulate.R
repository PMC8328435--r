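#' Generative truth configuration for synthetic data
#'
#' Default parameterization of the synthetic-data generator.  Demographic
#' means and regression coefficients default to the fitted posterior means
#' for the Yukon-Kuskokwim Delta population; residual random-effect SDs
#' for adult survival and nest success to the square roots of the
#' residual temporal variances of the covariate model (0.59 and 0.64 on
#' the logit scale); study dimensions to the 23-year study with ~30
#' duckling and ~30 adult releases and ~60 monitored nests per year.
#' Quantities the study does not report (mean recapture probability,
#' first-year-survival and recapture random-effect SDs) are set to
#' field-plausible values documented in the methods vignette.
#'
#' @param T Number of study years.
#' @param start_year First calendar year.
#' @param mean_phia,mean_phij,alpha,mean_p,mean_ns,cs,ds Demographic
#'   means: adult survival, first-year survival, 2-year-old breeding
#'   propensity, recapture, nest success, clutch size, duckling survival.
#' @param sigma_phia,sigma_phij,sigma_p,sigma_ns Logit-scale SDs of the
#'   annual random effects.
#' @param betas Named list of regression coefficients (logit scale):
#'   `phia_lin`, `phia_quad` (ice days on adult survival), `phij_ao`
#'   (Arctic Oscillation on first-year survival), `ns_lin`, `ns_quad`,
#'   `ns_fox`, `ns_precip` (nest success).
#' @param init Initial stage abundances `(n1, n2, n3, n4)`.
#' @param sigma_y_cv Observation-error SD as a fraction of true breeding
#'   abundance (aerial-survey scale), or `NULL` to supply `sigma_y`.
#' @param sigma_y Optional explicit per-year observation SDs.
#' @param ducklings_per_year,adults_per_year New releases per occasion.
#' @param nests_per_year Nests monitored per year.
#' @param missing_count_year Index of the unsurveyed count year (mimicking
#'   the 2011 gap; `NA` for none).
#' @param ice_rho,ice_load,ice_peak,ice_width,ice_base,ice_noise Winter
#'   severity generator: AR(1) correlation of the latent severity, its
#'   loading on the daily logit concentration, and the seasonal logistic
#'   curve's peak height, width (days), baseline and daily noise SD.
#' @return A list of class `ipm_truth`.
#' @export
ipm_truth <- function(T = 23, start_year = 1992,
                      mean_phia = 0.878, mean_phij = 0.290, alpha = 0.359,
                      mean_p = 0.5, mean_ns = 0.778, cs = 4.297, ds = 0.67,
                      sigma_phia = sqrt(0.59), sigma_phij = 0.5,
                      sigma_p = 0.3, sigma_ns = sqrt(0.64),
                      betas = list(phia_lin = -0.132, phia_quad = -0.251,
                                   phij_ao = 0.201, ns_lin = -0.026,
                                   ns_quad = -0.455, ns_fox = -0.169,
                                   ns_precip = -0.032),
                      init = c(n1 = 600, n2 = 100, n3 = 50, n4 = 1100),
                      sigma_y_cv = 0.08, sigma_y = NULL,
                      ducklings_per_year = 30, adults_per_year = 30,
                      nests_per_year = 60, missing_count_year = 20,
                      ice_rho = 0.6, ice_load = 0.85, ice_peak = 5.5,
                      ice_width = 60, ice_base = -1, ice_noise = 0.3) {
  stopifnot(T >= 3)
  probs <- c(mean_phia, mean_phij, alpha, mean_p, mean_ns)
  if (any(probs <= 0) || any(probs >= 1))
    stop("mean probabilities must lie in (0, 1)")
  structure(as.list(environment()), class = "ipm_truth")
}

#' Simulate winter sea-ice and annual covariate series
#'
#' Winter severity follows a stationary AR(1) latent process; each day's
#' ice concentration is an inverse-logit of a seasonal bell curve plus the
#' winter's severity and daily noise, so extreme-ice-day counts vary
#' smoothly across winters and span roughly the observed historical
#' spread.  Arctic Oscillation, fox-sign, and precipitation indices are
#' independent standard-normal annual draws (raw scale; standardization
#' happens downstream).
#'
#' @param truth An [ipm_truth()] configuration.
#' @return A list: `ice` (daily data.frame `date`, `concentration`),
#'   `annual` (data.frame `year`, `ao`, `fox`, `precip`), and
#'   `ice_days_true` (the generator's own per-winter extreme-ice-day
#'   counts, for bookkeeping checks).
#' @export
simulate_covariates <- function(truth) {
  years <- truth$start_year + seq_len(truth$T) - 1
  z <- numeric(truth$T)
  z[1] <- stats::rnorm(1)
  for (w in seq_len(truth$T - 1))
    z[w + 1] <- truth$ice_rho * z[w] + sqrt(1 - truth$ice_rho^2) * stats::rnorm(1)
  dates <- list(); conc <- list(); counts <- integer(truth$T)
  for (w in seq_len(truth$T)) {
    window <- winter_window(years[w])
    d <- seq_along(window)
    eta <- truth$ice_base +
      truth$ice_peak * exp(-((d - 90) / truth$ice_width)^2) +
      truth$ice_load * z[w] +
      stats::rnorm(length(d), 0, truth$ice_noise)
    cc <- stats::plogis(eta)
    counts[w] <- sum(cc >= 0.95)
    dates[[w]] <- window
    conc[[w]] <- cc
  }
  list(ice = data.frame(date = as.Date(unlist(dates), origin = "1970-01-01"),
                        concentration = unlist(conc)),
       annual = data.frame(year = years,
                           ao = stats::rnorm(truth$T),
                           fox = stats::rnorm(truth$T),
                           precip = stats::rnorm(truth$T)),
       ice_days_true = stats::setNames(counts, years))
}

#' Simulate annual demographic rates and the latent population
#'
#' Annual rates are built from the truth's logit-scale linear predictors
#' (standardized covariates plus Normal random effects); the stage
#' structure is propagated with the stochastic projection
#' ([project_stochastic()]), keeping latent states integer.
#'
#' @param truth An [ipm_truth()] configuration.
#' @param covariates Output of [simulate_covariates()].
#' @return A list: `stages` (4 x T integer matrix), `rates` (annual
#'   `phi_a`, `phi_j`, `ns`, `p`, `fec`), `eps` (the random-effect draws),
#'   `cov` (standardized covariate data.frame), and `extinct` (flag; the
#'   caller may redraw).
#' @export
simulate_population <- function(truth, covariates) {
  years <- truth$start_year + seq_len(truth$T) - 1
  cov <- build_annual_covariates(covariates$ice, covariates$annual, years)
  eps <- list(phia = stats::rnorm(truth$T - 1, 0, truth$sigma_phia),
              phij = stats::rnorm(truth$T - 1, 0, truth$sigma_phij),
              p    = stats::rnorm(truth$T - 1, 0, truth$sigma_p),
              ns   = stats::rnorm(truth$T, 0, truth$sigma_ns))
  params <- list(mean_phia = truth$mean_phia, mean_phij = truth$mean_phij,
                 alpha = truth$alpha, mean_p = truth$mean_p,
                 mean_ns = truth$mean_ns, cs = truth$cs,
                 eps_phia = eps$phia, eps_phij = eps$phij,
                 eps_p = eps$p, eps_ns = eps$ns, betas = truth$betas)
  rates <- annual_rates(params, cov, truth$T, truth$ds)
  n <- matrix(0L, 4, truth$T, dimnames = list(paste0("n", 1:4), years))
  n[, 1] <- as.integer(truth$init)
  sv <- stage_vector(n[1, 1], n[2, 1], n[3, 1], n[4, 1], year = years[1])
  for (t in seq_len(truth$T - 1)) {
    sv <- project_stochastic(sv, demographic_rates(
      rates$phi_j[t], rates$phi_a[t], truth$alpha, rates$fec[t]))
    n[, t + 1] <- as.integer(sv)
  }
  list(stages = n, rates = rates, eps = eps, cov = cov,
       extinct = any(colSums(n) == 0))
}

#' Simulate aerial-survey breeding-abundance counts
#'
#' @param stages 4 x T latent stage matrix (from [simulate_population()]).
#' @param sigma_y Per-year observation SDs (recycled).
#' @param years Calendar years.
#' @param missing Indices of unsurveyed years (count set to `NA`).
#' @return A data.frame `year`, `y`, `sigma_y`.
#' @export
simulate_counts <- function(stages, sigma_y, years, missing = integer(0)) {
  Nbpop <- 2 * (stages[3, ] + stages[4, ])
  sigma_y <- rep_len(sigma_y, length(Nbpop))
  y <- stats::rnorm(length(Nbpop), Nbpop, sigma_y)
  if (length(missing)) {
    if (any(missing < 1 | missing > length(y)))
      stop("missing-year indices outside the study years")
    y[missing] <- NA_real_
  }
  data.frame(year = years, y = y, sigma_y = sigma_y)
}

#' Simulate individual capture histories
#'
#' Individual-based emulation of the multistate life cycle, sharing the
#' annual rate values with the population process.  Ducklings survive
#' their first year with `phi_j`, their second with `phi_a`, breed at age
#' 2 with probability `alpha` (else certainly at age 3), and are
#' detectable only while breeding; adults are marked as breeders and
#' remain so.  Detection uses the shared annual recapture probabilities.
#'
#' @param truth An [ipm_truth()] configuration.
#' @param rates Annual rates from [simulate_population()] (`phi_a`,
#'   `phi_j`, `p` as interval/occasion series).
#' @return A [read_capture_histories()] object.
#' @export
simulate_cmr <- function(truth, rates) {
  T <- truth$T
  years <- truth$start_year + seq_len(T) - 1
  p_occ <- c(NA_real_, rates$p)  # occasion-indexed; occasion 1 unused
  rows <- list(); k <- 0L
  walk_adult <- function(det, occ) {
    # breeder alive at occasion occ (already detected there or at marking)
    while (occ < T) {
      if (stats::rbinom(1, 1, rates$phi_a[occ]) == 0) break
      occ <- occ + 1
      det[occ] <- stats::rbinom(1, 1, p_occ[occ])
    }
    det
  }
  for (t in seq_len(T - 1)) {
    for (i in seq_len(truth$adults_per_year)) {
      det <- integer(T); det[t] <- 1L
      det <- walk_adult(det, t)
      k <- k + 1L
      rows[[k]] <- c(id = sprintf("A%04d", k), cohort = "adult",
                     first_year = years[t], det)
    }
    for (i in seq_len(truth$ducklings_per_year)) {
      det <- integer(T); det[t] <- 1L
      if (t + 1 <= T && stats::rbinom(1, 1, rates$phi_j[t]) == 1 &&
          t + 2 <= T && stats::rbinom(1, 1, rates$phi_a[t + 1]) == 1) {
        if (stats::rbinom(1, 1, truth$alpha) == 1) {
          # breeds at age 2
          det[t + 2] <- stats::rbinom(1, 1, p_occ[t + 2])
          det <- walk_adult(det, t + 2)
        } else if (t + 3 <= T && stats::rbinom(1, 1, rates$phi_a[t + 2]) == 1) {
          # unobservable non-breeder at age 2; breeds at age 3
          det[t + 3] <- stats::rbinom(1, 1, p_occ[t + 3])
          det <- walk_adult(det, t + 3)
        }
      }
      k <- k + 1L
      rows[[k]] <- c(id = sprintf("D%04d", k), cohort = "duckling",
                     first_year = years[t], det)
    }
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("id", "cohort", "first_year", years)
  df$first_year <- as.integer(df$first_year)
  for (y in as.character(years)) df[[y]] <- as.integer(df[[y]])
  # adults are marked when detected breeding; their first detection IS the
  # marking event, so det[first] = 1 by construction for both cohorts
  read_capture_histories(df)
}

#' Simulate annual nest records
#'
#' @param truth An [ipm_truth()] configuration.
#' @param ns Annual nest-success probabilities (length T).
#' @return A nest data.frame with list-column `clutches`, as produced by
#'   [read_nest_data()].
#' @export
simulate_nests <- function(truth, ns) {
  years <- truth$start_year + seq_len(truth$T) - 1
  nn <- rep(truth$nests_per_year, truth$T)
  succ <- stats::rbinom(truth$T, nn, ns)
  df <- data.frame(year = years, n_nests = nn, n_success = succ)
  df$clutches <- lapply(succ, function(s) as.integer(stats::rpois(s, truth$cs)))
  df
}

#' Simulate a complete synthetic data bundle
#'
#' Draws the covariate series, latent population, counts, capture
#' histories, and nest records from one shared set of annual rate values
#' (so every data stream is mutually consistent), redrawing up to
#' `max_tries` times in the (practically impossible at default sizes)
#' event of extinction.
#'
#' @param truth An [ipm_truth()] configuration.
#' @param seed Integer seed; recorded in the bundle.
#' @param max_tries Redraws allowed on extinction.
#' @return A list of class `ipm_bundle`: `counts`, `histories`, `nests`,
#'   `ice`, `annual`, `truth` (including the realized `stages`, `rates`,
#'   and `seed`).
#' @export
simulate_ipm_data <- function(truth = ipm_truth(), seed = NULL, max_tries = 20) {
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(max_tries)) {
    covs <- simulate_covariates(truth)
    pop <- simulate_population(truth, covs)
    if (!pop$extinct) break
    if (try == max_tries) stop("population went extinct in every redraw")
  }
  years <- truth$start_year + seq_len(truth$T) - 1
  sigma_y <- if (!is.null(truth$sigma_y)) rep_len(truth$sigma_y, truth$T)
             else truth$sigma_y_cv * 2 * (pop$stages[3, ] + pop$stages[4, ])
  missing <- if (is.na(truth$missing_count_year)) integer(0)
             else intersect(truth$missing_count_year, seq_len(truth$T))
  counts <- simulate_counts(pop$stages, sigma_y, years, missing)
  histories <- simulate_cmr(truth, pop$rates)
  nests <- simulate_nests(truth, pop$rates$ns)
  meta <- truth
  meta$seed <- seed
  meta$stages <- pop$stages
  meta$rates <- pop$rates
  meta$eps <- pop$eps
  meta$ice_days_true <- covs$ice_days_true
  structure(list(counts = counts, histories = histories, nests = nests,
                 ice = covs$ice, annual = covs$annual, truth = meta),
            class = "ipm_bundle")
}

#' Assemble an [ipm_data()] bundle from simulated or read data
#'
#' @param bundle An `ipm_bundle` (from [simulate_ipm_data()] or
#'   [read_bundle()]).
#' @param covariates Include the standardized covariates (`TRUE`) or build
#'   the temporal-variation data bundle (`FALSE`).
#' @param mask_years Years excluded from covariate standardization.
#' @return An [ipm_data()] object.
#' @export
as_ipm_data <- function(bundle, covariates = TRUE, mask_years = integer(0)) {
  years <- attr(bundle$histories, "years")
  cov <- if (covariates)
    build_annual_covariates(bundle$ice, bundle$annual, years, mask_years)
  else NULL
  ipm_data(bundle$counts, bundle$histories, bundle$nests, cov,
           ds = if (!is.null(bundle$truth$ds)) bundle$truth$ds else 0.67)
}

#' Write a synthetic bundle to CSV files plus truth metadata
#'
#' Writes `counts.csv`, `capture_histories.csv`, `nests.csv`,
#' `ice_daily.csv`, `covariates_annual.csv`, and `truth.json` (the full
#' generative parameterization, including the seed) into `dir`.
#'
#' @param bundle An `ipm_bundle`.
#' @param dir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0 && !force)
    stop("directory ", dir, " is not empty; use force = TRUE to overwrite")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$counts, file.path(dir, "counts.csv"), row.names = FALSE)
  h <- as.data.frame(bundle$histories)
  utils::write.csv(h, file.path(dir, "capture_histories.csv"), row.names = FALSE)
  nests <- bundle$nests
  nests$clutch_sizes <- vapply(nests$clutches, paste, character(1), collapse = ";")
  nests$clutches <- NULL
  utils::write.csv(nests, file.path(dir, "nests.csv"), row.names = FALSE)
  utils::write.csv(bundle$ice, file.path(dir, "ice_daily.csv"), row.names = FALSE)
  utils::write.csv(bundle$annual, file.path(dir, "covariates_annual.csv"),
                   row.names = FALSE)
  truth <- unclass(bundle$truth)
  truth$stages <- NULL; truth$rates <- NULL; truth$eps <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a bundle written by [write_bundle()]
#'
#' @param dir Directory containing the bundle CSVs.
#' @return A list of class `ipm_bundle` (with `truth` when `truth.json`
#'   is present).
#' @export
read_bundle <- function(dir) {
  counts <- utils::read.csv(file.path(dir, "counts.csv"))
  histories <- read_capture_histories(file.path(dir, "capture_histories.csv"))
  nests <- read_nest_data(file.path(dir, "nests.csv"))
  ice <- read_ice_series(file.path(dir, "ice_daily.csv"))
  annual <- utils::read.csv(file.path(dir, "covariates_annual.csv"))
  tf <- file.path(dir, "truth.json")
  truth <- if (file.exists(tf)) jsonlite::read_json(tf, simplifyVector = TRUE) else NULL
  structure(list(counts = counts, histories = histories, nests = nests,
                 ice = ice, annual = annual, truth = truth),
            class = "ipm_bundle")
}
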