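#' Prior set for the integrated population model
#'
#' Empirically motivated priors: Beta priors on the mean demographic
#' probabilities (moment-matched to mean/SD stated for each rate),
#' Gamma(0.1, 0.1) on clutch size, Uniform(0.001, 5) on all
#' random-effect SDs, Normal(0, 10) on regression coefficients, and
#' discrete-uniform bounds on the initial stage abundances.
#'
#' @return A list of class `ipm_priors` with elements `phi_a`, `phi_j`,
#'   `alpha`, `p`, `ns` (Beta shape pairs), `cs` (Gamma shape/rate),
#'   `sigma` (Uniform bounds), `beta_sd` (Normal SD), and `init` (a list
#'   of lower/upper bounds per stage).
#' @examples
#' pr <- default_priors()
#' prior_means(pr)  # 0.75, 0.30, 0.30, 0.50, 0.65
#' @export
default_priors <- function() {
  structure(list(
    phi_a = c(5.5, 1.833),
    phi_j = c(2.5, 5.833),
    alpha = c(2.5, 5.833),
    p     = c(5.056, 5.056),
    ns    = c(5.922, 3.189),
    cs    = c(0.1, 0.1),
    sigma = c(0.001, 5),
    beta_sd = 10,
    init = list(n1 = c(300, 900), n2 = c(10, 200),
                n3 = c(10, 100), n4 = c(500, 2000))
  ), class = "ipm_priors")
}

#' Means of the Beta priors on demographic probabilities
#' @param priors A prior set from [default_priors()].
#' @return Named vector of prior means (`a / (a + b)` per rate).
#' @export
prior_means <- function(priors = default_priors()) {
  vapply(priors[c("phi_a", "phi_j", "alpha", "p", "ns")],
         function(ab) ab[1] / (ab[1] + ab[2]), numeric(1))
}

#' Bundle the four data streams for fitting
#'
#' @param counts data.frame `year`, `y` (breeding-abundance estimate;
#'   `NA` for unsurveyed years), `sigma_y` (per-year observation SD).
#' @param histories A [read_capture_histories()] object.
#' @param nests Nest data from [read_nest_data()].
#' @param covariates Standardized covariates from
#'   [build_annual_covariates()] (may be `NULL` for the temporal-variation
#'   model).
#' @param ds Duckling survival constant (data, not a parameter).
#' @return A list of class `ipm_data`.
#' @export
ipm_data <- function(counts, histories, nests, covariates = NULL, ds = 0.67) {
  years <- attr(histories, "years")
  stopifnot(is.data.frame(counts), all(c("year", "y", "sigma_y") %in% names(counts)))
  if (!identical(as.integer(counts$year), as.integer(years)))
    stop("count years must match the capture-history study years")
  if (!identical(as.integer(nests$year), as.integer(years)))
    stop("nest years must match the capture-history study years")
  if (any(counts$sigma_y[!is.na(counts$y)] <= 0, na.rm = TRUE))
    stop("sigma_y must be positive where counts are observed")
  if (!is.null(covariates) &&
      !identical(as.integer(covariates$year), as.integer(years)))
    stop("covariate years must match the study years")
  structure(list(counts = counts, histories = histories, nests = nests,
                 covariates = covariates, ds = ds, years = years),
            class = "ipm_data")
}

#' Normal log-likelihood of the breeding-abundance counts
#'
#' `Y_t ~ Normal(Nbpop_t, sigma_y_t)` for surveyed years; years with a
#' missing count (e.g. a year with no aerial survey) contribute nothing.
#'
#' @param y Observed breeding-abundance estimates (`NA` = unsurveyed).
#' @param sigma_y Per-year observation SDs.
#' @param Nbpop Latent breeding abundance per year.
#' @return Log-likelihood over the non-missing years.
#' @export
count_loglik <- function(y, sigma_y, Nbpop) {
  if (length(y) != length(Nbpop) || length(y) != length(sigma_y))
    stop("y, sigma_y and Nbpop must have equal length")
  obs <- !is.na(y)
  if (!any(obs)) return(0)
  if (any(!is.finite(sigma_y[obs])) || any(sigma_y[obs] <= 0))
    stop("sigma_y must be positive for observed counts")
  sum(stats::dnorm(y[obs], Nbpop[obs], sigma_y[obs], log = TRUE))
}

#' Marginal count likelihood with the latent stages integrated out
#'
#' Gaussian (Kalman-filter) marginalization of the stochastic stage
#' process: the Poisson/trinomial/binomial transitions are moment-matched
#' by a Normal process with mean given by the projection matrix and
#' covariance from the plug-in transition variances, and the latent
#' stages are integrated out analytically.  This is the likelihood behind
#' the default `process = "marginal"` sampler mode; the exact
#' discrete-latent process remains available as a sampling fallback.
#'
#' @param rates List of annual rates: `phi_j`, `phi_a` (length `T - 1`)
#'   and `fec` (length `T`, last element unused).
#' @param alpha Breeding probability of 2-year-olds.
#' @param y Observed counts (`NA` = unsurveyed).
#' @param sigma_y Observation SDs (used where `y` is observed).
#' @param init_mean,init_var Mean and variance of the independent initial
#'   stage priors (defaults: moments of the discrete-uniform priors).
#' @return The marginal log-likelihood, with attributes `yhat` and `S`
#'   (one-step-ahead predicted counts and their variances, incl.
#'   observation error) and `m_filt` (4 x T filtered stage means).
#' @export
count_marginal_loglik <- function(rates, alpha, y, sigma_y,
                                  init_mean = NULL, init_var = NULL) {
  priors <- default_priors()
  if (is.null(init_mean))
    init_mean <- vapply(priors$init, function(b) mean(b), numeric(1))
  if (is.null(init_var))
    init_var <- vapply(priors$init, function(b) ((b[2] - b[1] + 1)^2 - 1) / 12,
                       numeric(1))
  T <- length(y)
  H <- c(0, 0, 2, 2)
  m <- init_mean
  P <- diag(init_var)
  ll <- 0
  yhat <- S <- rep(NA_real_, T)
  m_filt <- matrix(NA_real_, 4, T)
  for (t in seq_len(T)) {
    yhat[t] <- sum(H * m)
    sv2 <- if (!is.na(y[t])) sigma_y[t]^2
           else if (any(!is.na(y))) mean(sigma_y[!is.na(y)]^2) else 0
    S[t] <- drop(H %*% P %*% H) + sv2
    if (!is.na(y[t])) {
      ll <- ll + stats::dnorm(y[t], yhat[t], sqrt(S[t]), log = TRUE)
      K <- drop(P %*% H) / S[t]
      m <- m + K * (y[t] - yhat[t])
      P <- P - outer(K, drop(H %*% P))
    }
    m_filt[, t] <- m
    if (t < T) {
      A <- projection_matrix(demographic_rates(rates$phi_j[t], rates$phi_a[t],
                                               alpha, rates$fec[t]))
      lam <- rates$fec[t] / 2 * rates$phi_j[t] * (m[3] + m[4])
      p2 <- rates$phi_a[t] * (1 - alpha)
      p3 <- rates$phi_a[t] * alpha
      m1 <- max(m[1], 0)
      m234 <- max(m[2] + m[3] + m[4], 0)
      Q <- matrix(0, 4, 4)
      Q[1, 1] <- max(lam, 1e-6)
      Q[2, 2] <- m1 * p2 * (1 - p2)
      Q[3, 3] <- m1 * p3 * (1 - p3)
      Q[2, 3] <- Q[3, 2] <- -m1 * p2 * p3
      Q[4, 4] <- m234 * rates$phi_a[t] * (1 - rates$phi_a[t])
      m <- drop(A %*% m)
      P <- A %*% P %*% t(A) + Q
    }
  }
  structure(ll, yhat = yhat, S = S, m_filt = m_filt)
}

## Annual rates implied by a parameter set ------------------------------

# Covariate alignment: survival over interval t -> t+1 (and first-year
# survival over the same interval) uses the winter ending in year t+1;
# nest success of breeding season t uses the winter ending in April of
# year t.
annual_rates <- function(params, covariates, T, ds = 0.67) {
  z <- function(col) {
    if (is.null(covariates)) rep(0, T) else covariates[[col]]
  }
  b <- params$betas
  bv <- function(name) if (is.null(b) || is.null(b[[name]])) 0 else b[[name]]
  ice <- z("ice_days"); ao <- z("ao"); fox <- z("fox"); precip <- z("precip")
  ti <- seq_len(T - 1)
  phi_a <- linear_predictor_phiA(stats::qlogis(params$mean_phia),
                                 params$eps_phia, ice[ti + 1],
                                 bv("phia_lin"), bv("phia_quad"), prob = TRUE)
  phi_j <- linear_predictor_phiJ(stats::qlogis(params$mean_phij),
                                 params$eps_phij, ao[ti + 1],
                                 bv("phij_ao"), prob = TRUE)
  ns <- linear_predictor_ns(stats::qlogis(params$mean_ns), params$eps_ns,
                            ice, fox, precip,
                            bv("ns_lin"), bv("ns_quad"),
                            bv("ns_fox"), bv("ns_precip"), prob = TRUE)
  p <- stats::plogis(stats::qlogis(params$mean_p) + params$eps_p)
  list(phi_a = phi_a, phi_j = phi_j, ns = ns, p = p,
       fec = fecundity(ns, params$cs, ds))
}

log_ddunif <- function(x, bounds) {
  ifelse(x >= bounds[1] & x <= bounds[2] & x == round(x),
         -log(bounds[2] - bounds[1] + 1), -Inf)
}

#' Joint log-density of the integrated population model
#'
#' Log-priors (hyperparameters and random effects), the latent
#' state-process log-probability, and the three data likelihoods (counts,
#' capture-recapture, productivity), summed.  The components are exactly
#' additive and returned in a `"components"` attribute with `-Inf`
#' attribution.  Parameters absent from `params` (e.g. `betas` in the
#' temporal-variation model) are treated as fixed and contribute no prior
#' term, so the covariate model evaluated at `betas = 0` equals the
#' temporal-variation model exactly.
#'
#' @param params Named list: `mean_phia`, `mean_phij`, `alpha`, `mean_p`,
#'   `mean_ns`, `cs`, `sigma_phia`, `sigma_phij`, `sigma_p`, `sigma_ns`,
#'   random-effect vectors `eps_phia`, `eps_phij` (length `T - 1`),
#'   `eps_p` (length `T - 1`, occasions `2:T`), `eps_ns` (length `T`),
#'   optional `betas` (list), and optional latent-state matrix `n`
#'   (`4 x T`).
#' @param data An [ipm_data()] bundle.
#' @param priors A prior set from [default_priors()].
#' @param process `"stochastic"` (Poisson/binomial latent transitions) or
#'   `"deterministic"` (latent states are a deterministic projection; only
#'   the initial state carries prior mass).
#' @return The joint log-density, with a `components` attribute.
#' @export
log_joint <- function(params, data, priors = default_priors(),
                      process = c("stochastic", "deterministic")) {
  process <- match.arg(process)
  stopifnot(inherits(data, "ipm_data"))
  T <- length(data$years)
  comp <- c(prior = 0, raneff = 0, process = 0, count = 0, cmr = 0,
            nest_success = 0, clutch = 0)

  db <- function(x, ab) stats::dbeta(x, ab[1], ab[2], log = TRUE)
  comp["prior"] <- db(params$mean_phia, priors$phi_a) +
    db(params$mean_phij, priors$phi_j) +
    db(params$alpha, priors$alpha) +
    db(params$mean_p, priors$p) +
    db(params$mean_ns, priors$ns) +
    stats::dgamma(params$cs, priors$cs[1], priors$cs[2], log = TRUE) +
    sum(stats::dunif(c(params$sigma_phia, params$sigma_phij,
                       params$sigma_p, params$sigma_ns),
                     priors$sigma[1], priors$sigma[2], log = TRUE))
  if (!is.null(params$betas))
    comp["prior"] <- comp["prior"] +
      sum(stats::dnorm(unlist(params$betas), 0, priors$beta_sd, log = TRUE))

  comp["raneff"] <- sum(stats::dnorm(params$eps_phia, 0, params$sigma_phia, log = TRUE)) +
    sum(stats::dnorm(params$eps_phij, 0, params$sigma_phij, log = TRUE)) +
    sum(stats::dnorm(params$eps_p, 0, params$sigma_p, log = TRUE)) +
    sum(stats::dnorm(params$eps_ns, 0, params$sigma_ns, log = TRUE))

  rates <- annual_rates(params, data$covariates, T, data$ds)

  if (!is.null(params$n)) {
    n <- params$n
    comp["process"] <- sum(vapply(seq_along(priors$init), function(i)
      log_ddunif(n[i, 1], priors$init[[i]]), numeric(1)))
    if (process == "stochastic") {
      for (t in seq_len(T - 1)) {
        lam <- rates$fec[t] / 2 * rates$phi_j[t] * (n[3, t] + n[4, t])
        comp["process"] <- comp["process"] +
          stats::dpois(n[1, t + 1], lam, log = TRUE) +
          stats::dmultinom(c(n[2, t + 1], n[3, t + 1],
                             n[1, t] - n[2, t + 1] - n[3, t + 1]),
                           prob = c(rates$phi_a[t] * (1 - params$alpha),
                                    rates$phi_a[t] * params$alpha,
                                    1 - rates$phi_a[t]), log = TRUE) +
          stats::dbinom(n[4, t + 1], n[2, t] + n[3, t] + n[4, t],
                        rates$phi_a[t], log = TRUE)
      }
    } else {
      for (t in seq_len(T - 1)) {
        sv <- stage_vector(n[1, t], n[2, t], n[3, t], n[4, t])
        pred <- project_deterministic(sv, demographic_rates(
          rates$phi_j[t], rates$phi_a[t], params$alpha, rates$fec[t]))
        if (max(abs(as.numeric(pred) - n[, t + 1])) > 1e-6)
          comp["process"] <- -Inf
      }
    }
    Nbpop <- 2 * (n[3, ] + n[4, ])
    comp["count"] <- count_loglik(data$counts$y, data$counts$sigma_y, Nbpop)
  }

  p_occ <- c(NA, rates$p)  # occasion-indexed, p[1] never used
  p_occ[1] <- 0.5
  marr_a <- build_marray(data$histories, "adult")
  marr_d <- build_marray(data$histories, "duckling")
  comp["cmr"] <- cmr_loglik(marr_a, adult_cell_probabilities(rates$phi_a, p_occ)) +
    cmr_loglik(marr_d, duckling_cell_probabilities(rates$phi_j, rates$phi_a,
                                                   params$alpha, p_occ))
  comp["nest_success"] <- nest_success_loglik(data$nests, rates$ns)
  comp["clutch"] <- clutch_loglik(data$nests, params$cs)

  structure(sum(comp), components = comp)
}
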