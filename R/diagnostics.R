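#' Gelman-Rubin potential scale reduction factor
#'
#' Classic two-part R-hat: with `m` chains of `n` kept draws, the
#' within-chain variance `W` is the mean of the chain variances, the
#' between-chain variance `B` is `n` times the variance of the chain
#' means, and `R-hat = sqrt(((n-1)/n * W + B/n) / W)`.  Values at or
#' below 1.05 are taken as converged.
#'
#' @param x A draws-by-chains matrix (>= 2 chains), or a `coda::mcmc.list`
#'   for a single parameter.
#' @return The R-hat statistic.
#' @export
rhat <- function(x) {
  if (inherits(x, "mcmc.list")) x <- sapply(x, as.numeric)
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("R-hat requires at least two chains")
  n <- nrow(x)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(colMeans(x))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

rhat_all <- function(samples) {
  if (length(samples) < 2)
    return(stats::setNames(rep(NA_real_, ncol(samples[[1]])),
                           colnames(samples[[1]])))
  mats <- lapply(samples, as.matrix)
  vapply(seq_len(ncol(mats[[1]])), function(j)
    rhat(sapply(mats, function(m) m[, j])), numeric(1)) |>
    stats::setNames(colnames(mats[[1]]))
}

#' Proportion of temporal variance explained by covariates
#'
#' `V = (sigma2_total - sigma2_resid) / sigma2_total`, comparing the
#' residual temporal variance of a demographic rate under the
#' temporal-variation model with that under the environmental-covariates
#' model (both on the logit scale).
#'
#' @param sigma2_total Total temporal variance (temporal-variation model).
#' @param sigma2_resid Residual variance (covariate model).
#' @return The proportion explained; negative (with a warning) when the
#'   residual estimate exceeds the total, which can happen under
#'   estimation noise.
#' @examples
#' variance_explained(0.71, 0.59)  # ~0.17 for adult survival
#' variance_explained(1.13, 0.64)  # ~0.43 for nest success
#' @export
variance_explained <- function(sigma2_total, sigma2_resid) {
  if (!is.finite(sigma2_total) || !is.finite(sigma2_resid) ||
      sigma2_total <= 0 || sigma2_resid <= 0)
    stop("variances must be positive")
  V <- (sigma2_total - sigma2_resid) / sigma2_total
  if (V < 0) warning("residual variance exceeds total; V is negative")
  V
}

#' Posterior mode by kernel density
#'
#' Argmax of a Gaussian kernel density estimate with Silverman's
#' rule-of-thumb bandwidth.
#'
#' @param x Numeric draws.
#' @return The mode estimate.
#' @export
posterior_mode <- function(x) {
  x <- x[is.finite(x)]
  if (length(unique(x)) == 1) return(x[1])
  d <- stats::density(x, bw = "nrd0")
  d$x[which.max(d$y)]
}

#' Freeman-Tukey posterior-predictive check for the nest-success model
#'
#' For each posterior draw, the observed discrepancy is
#' `D_obs = sum_t (sqrt(succ_t) - sqrt(nn_t * ns_t))^2` and the
#' replicated discrepancy recomputes it on binomial data simulated from
#' the same draw.  The Bayesian p-value is the fraction of draws with
#' `D_rep >= D_obs`; values near 0.5 indicate adequate fit.
#'
#' @param fit An `eider_ipm` fit (or a draws x years matrix of `ns`).
#' @param nests Nest data; defaults to the data bundle inside `fit`.
#' @param seed Optional seed for the replicate draws.
#' @return A list: `p_value`, `D_obs`, `D_rep` (per-draw discrepancies).
#' @export
gof_freeman_tukey <- function(fit, nests = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ns <- if (inherits(fit, "eider_ipm")) posterior_matrix(fit, "ns") else as.matrix(fit)
  if (is.null(nests)) nests <- fit$data$nests
  nn <- nests$n_nests; succ <- nests$n_success
  expd <- sweep(ns, 2, nn, `*`)
  D_obs <- rowSums(sweep(sqrt(expd), 2, sqrt(succ), function(e, o) (o - e)^2))
  rep_succ <- matrix(stats::rbinom(length(ns), size = rep(nn, each = nrow(ns)),
                                   prob = ns), nrow(ns))
  D_rep <- rowSums((sqrt(rep_succ) - sqrt(expd))^2)
  list(p_value = mean(D_rep >= D_obs), D_obs = D_obs, D_rep = D_rep)
}

#' Chi-square posterior-predictive check for the count model
#'
#' Per draw, `X2_obs = sum_t (y_t - Nbpop_t)^2 / sigma_y_t^2` over
#' surveyed years, against the same statistic on replicate Normal counts.
#' For fits with sampled latent states, `Nbpop` and `sigma_y` are used
#' directly; for marginal-process fits (latent stages integrated out) the
#' statistic uses the one-step-ahead predictions and their variances --
#' the prediction-error (innovation) form of the same discrepancy.
#'
#' @param fit An `eider_ipm` fit.
#' @param counts Count data; defaults to the bundle inside `fit`.
#' @param seed Optional seed for the replicate draws.
#' @return A list: `p_value`, `X2_obs`, `X2_rep`.
#' @export
gof_chisq_counts <- function(fit, counts = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(counts)) counts <- fit$data$counts
  obs <- which(!is.na(counts$y))
  y <- counts$y[obs]
  marginal <- inherits(fit, "eider_ipm") &&
    identical(fit$config$process, "marginal")
  if (marginal) {
    mu <- posterior_matrix(fit, "yhat")[, obs, drop = FALSE]
    v <- posterior_matrix(fit, "S")[, obs, drop = FALSE]
  } else {
    mu <- posterior_matrix(fit, "Nbpop")[, obs, drop = FALSE]
    v <- matrix(counts$sigma_y[obs]^2, nrow(mu), length(obs), byrow = TRUE)
  }
  X2_obs <- rowSums(sweep(mu, 2, y, function(m, y) (y - m)^2) / v)
  yrep <- mu + matrix(stats::rnorm(length(mu), 0, sqrt(v)), nrow(mu))
  X2_rep <- rowSums((yrep - mu)^2 / v)
  list(p_value = mean(X2_rep >= X2_obs), X2_obs = X2_obs, X2_rep = X2_rep)
}

#' Correlations between demographic rates and population growth
#'
#' For every posterior draw, the Pearson correlation across years between
#' each annual demographic rate (adult survival, first-year survival,
#' nest success, fecundity) and the growth rate of total female abundance
#' `lambda_t = Ntot_{t+1} / Ntot_t`.  Rates are aligned with the interval
#' their year index acts on (t = 1..T-1).  Draws in which either series
#' is constant (correlation undefined) are skipped and counted.
#'
#' @param fit An `eider_ipm` fit.
#' @param probs Credible-interval probabilities.
#' @return A data.frame with one row per rate: posterior mode, mean,
#'   median, CrI bounds, `p_gt0` (posterior probability the correlation
#'   is positive), and `n_skipped` degenerate draws.
#' @export
demographic_correlations <- function(fit, probs = c(0.025, 0.975)) {
  Ntot <- posterior_matrix(fit, "Ntot")
  T <- ncol(Ntot)
  if (T < 3) stop("need at least three years for growth correlations")
  lam <- Ntot[, -1, drop = FALSE] / Ntot[, -T, drop = FALSE]
  ti <- seq_len(T - 1)
  series <- list(phi_a = posterior_matrix(fit, "phi_a"),
                 phi_j = posterior_matrix(fit, "phi_j"),
                 ns = posterior_matrix(fit, "ns")[, ti, drop = FALSE],
                 fec = posterior_matrix(fit, "fec")[, ti, drop = FALSE])
  out <- lapply(names(series), function(nm) {
    x <- series[[nm]]
    r <- vapply(seq_len(nrow(x)), function(d) {
      if (stats::sd(x[d, ]) == 0 || stats::sd(lam[d, ]) == 0) return(NA_real_)
      stats::cor(x[d, ], lam[d, ])
    }, numeric(1))
    skipped <- sum(is.na(r))
    if (skipped) message(skipped, " draw(s) with constant series skipped for ", nm)
    r <- r[!is.na(r)]
    if (length(r) == 0)
      return(data.frame(rate = nm, mode = NA_real_, mean = NA_real_,
                        median = NA_real_, lower = NA_real_, upper = NA_real_,
                        p_gt0 = NA_real_, n_skipped = skipped))
    ci <- stats::quantile(r, probs, names = FALSE)
    data.frame(rate = nm, mode = posterior_mode(r), mean = mean(r),
               median = stats::median(r), lower = ci[1], upper = ci[2],
               p_gt0 = mean(r > 0), n_skipped = skipped)
  })
  do.call(rbind, out)
}

#' Posterior summary table for an IPM fit
#'
#' Table-style report: posterior mean, median, kernel-density mode, 95%
#' credible interval and R-hat for every scalar parameter, plus derived
#' geometric mean growth rates of the breeding population and of total
#' females (computed per draw from the latent abundances, so the
#' geometric-mean identity `(N_T / N_1)^(1/(T-1))` holds exactly).
#'
#' @param object An `eider_ipm` fit.
#' @param probs Credible-interval probabilities.
#' @param ... Unused.
#' @return A `summary.eider_ipm` object: data.frame of estimands.
#' @export
summary.eider_ipm <- function(object, probs = c(0.025, 0.975), ...) {
  mat <- as.matrix(object$samples)
  scalars <- c("mean_phia", "mean_phij", "alpha", "mean_p", "mean_ns", "cs",
               "sigma_phia", "sigma_phij", "sigma_p", "sigma_ns",
               "b_phia_lin", "b_phia_quad", "b_phij_ao", "b_ns_lin",
               "b_ns_quad", "b_ns_fox", "b_ns_precip")
  scalars <- intersect(scalars, colnames(mat))
  rows <- lapply(scalars, function(s) summ_row(s, mat[, s], object$rhat[s], probs))
  for (nm in c("Nbpop", "Ntot")) {
    N <- posterior_matrix(object, nm)
    gl <- apply(N, 1, function(v) geometric_mean_growth(lambda_series(v)))
    rows <- c(rows, list(summ_row(paste0("geo_lambda_", tolower(nm)), gl,
                                  NA_real_, probs)))
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("summary.eider_ipm", "data.frame"),
            config = object$config)
}

summ_row <- function(name, draws, rh, probs) {
  ci <- stats::quantile(draws, probs, names = FALSE)
  data.frame(parameter = name, mean = mean(draws),
             median = stats::median(draws), mode = posterior_mode(draws),
             lower = ci[1], upper = ci[2],
             rhat = if (is.null(rh)) NA_real_ else unname(rh))
}

#' @export
print.summary.eider_ipm <- function(x, digits = 3, ...) {
  cat("Posterior summaries (mean, median, mode, 95% CrI, R-hat)\n")
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Plot annual demographic estimates or covariate response curves
#'
#' `which = "rates"` draws the annual posterior means and 95% CrIs of
#' adult survival, first-year survival, nest success, and breeding
#' abundance.  `which = "response"` draws the posterior mean quadratic
#' response of adult survival and nest success to standardized ice days
#' on a grid (covariate fits only).
#'
#' @param x An `eider_ipm` fit.
#' @param which `"rates"` or `"response"`.
#' @param grid Standardized ice-days grid for response curves.
#' @param ... Unused.
#' @export
plot.eider_ipm <- function(x, which = c("rates", "response"),
                           grid = seq(-2.5, 2.5, length.out = 101), ...) {
  which <- match.arg(which)
  years <- x$data$years
  if (which == "rates") {
    op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    panels <- list(phi_a = "Adult survival", phi_j = "First-year survival",
                   ns = "Nest success", Nbpop = "Breeding abundance")
    for (nm in names(panels)) {
      m <- posterior_matrix(x, nm)
      yrs <- if (ncol(m) == length(years)) years else years[-length(years)]
      mu <- colMeans(m)
      lo <- apply(m, 2, stats::quantile, 0.025)
      hi <- apply(m, 2, stats::quantile, 0.975)
      graphics::plot(yrs, mu, ylim = range(lo, hi), pch = 16,
                     xlab = "Year", ylab = panels[[nm]])
      graphics::arrows(yrs, lo, yrs, hi, angle = 90, code = 3,
                       length = 0.02, lty = 2)
    }
  } else {
    if (!x$config$covariates) stop("response curves need a covariate fit")
    rc <- response_curves(x, grid)
    op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    for (nm in c("phi_a", "ns")) {
      cc <- rc[rc$rate == nm, ]
      graphics::plot(cc$ice, cc$mean, type = "l", ylim = range(cc$lower, cc$upper),
                     xlab = "Standardized ice days",
                     ylab = if (nm == "phi_a") "Adult survival" else "Nest success")
      graphics::lines(cc$ice, cc$lower, lty = 2)
      graphics::lines(cc$ice, cc$upper, lty = 2)
    }
  }
  invisible(x)
}

#' Posterior quadratic response curves on an ice-days grid
#'
#' Evaluates the fitted quadratic ice-day response of adult survival and
#' nest success (at average values of the other covariates and random
#' effects) over a standardized grid, with credible bands.
#'
#' @param fit A covariate-model `eider_ipm` fit.
#' @param grid Standardized ice-days values.
#' @param probs Credible-interval probabilities.
#' @return A data.frame: `rate`, `ice`, `mean`, `lower`, `upper`.
#' @export
response_curves <- function(fit, grid = seq(-2.5, 2.5, length.out = 101),
                            probs = c(0.025, 0.975)) {
  if (!fit$config$covariates) stop("response curves need a covariate fit")
  mat <- as.matrix(fit$samples)
  out <- list()
  specs <- list(phi_a = c(mu = "mean_phia", lin = "b_phia_lin", quad = "b_phia_quad"),
                ns = c(mu = "mean_ns", lin = "b_ns_lin", quad = "b_ns_quad"))
  for (nm in names(specs)) {
    s <- specs[[nm]]
    eta <- outer(stats::qlogis(mat[, s["mu"]]), rep(1, length(grid))) +
      outer(mat[, s["lin"]], grid) + outer(mat[, s["quad"]], grid^2)
    pr <- stats::plogis(eta)
    out[[nm]] <- data.frame(rate = nm, ice = grid, mean = colMeans(pr),
                            lower = apply(pr, 2, stats::quantile, probs[1]),
                            upper = apply(pr, 2, stats::quantile, probs[2]))
  }
  do.call(rbind, out)
}
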