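## JAGS model code for the integrated population model.
##
## Indexing conventions shared with the R-side likelihood functions:
##   phi_a[t], phi_j[t] act on interval t -> t+1 (t = 1..T-1)
##   p[t] is the recapture probability at occasion t+1 (t = 1..T-1)
##   ns[t], fec[t] belong to breeding season t (t = 1..T)
##   m-array column j is first recapture at occasion j+1; column T = never
jags_model_string <- function(covariates = TRUE,
                              process = c("marginal", "stochastic",
                                          "deterministic")) {
  process <- match.arg(process)
  cov_phia <- if (covariates) " + b_phia_lin * ice_surv[t] + b_phia_quad * ice_surv[t] * ice_surv[t]" else ""
  cov_phij <- if (covariates) " + b_phij_ao * ao_surv[t]" else ""
  cov_ns <- if (covariates) " + b_ns_lin * ice_ns[t] + b_ns_quad * ice_ns[t] * ice_ns[t] + b_ns_fox * fox[t] + b_ns_precip * precip[t]" else ""
  beta_priors <- if (covariates) "
  b_phia_lin ~ dnorm(0, beta_tau)
  b_phia_quad ~ dnorm(0, beta_tau)
  b_phij_ao ~ dnorm(0, beta_tau)
  b_ns_lin ~ dnorm(0, beta_tau)
  b_ns_quad ~ dnorm(0, beta_tau)
  b_ns_fox ~ dnorm(0, beta_tau)
  b_ns_precip ~ dnorm(0, beta_tau)" else ""
  state_proc <- if (process == "stochastic") "
    n1[t + 1] ~ dpois(fec[t] / 2 * phi_j[t] * (n3[t] + n4[t]))
    s1[t + 1] ~ dbin(phi_a[t], n1[t])
    n3[t + 1] ~ dbin(alpha, s1[t + 1])
    n2[t + 1] <- s1[t + 1] - n3[t + 1]
    n4[t + 1] ~ dbin(phi_a[t], n2[t] + n3[t] + n4[t])" else "
    n1[t + 1] <- fec[t] / 2 * phi_j[t] * (n3[t] + n4[t])
    n2[t + 1] <- phi_a[t] * (1 - alpha) * n1[t]
    n3[t + 1] <- phi_a[t] * alpha * n1[t]
    n4[t + 1] <- phi_a[t] * (n2[t] + n3[t] + n4[t])"
  count_block <- if (process == "marginal") "
  # marginalized latent process: the Poisson/trinomial/binomial stage
  # transitions are moment-matched by a Gaussian process and the latent
  # stages integrated out by a Kalman recursion (prediction-error
  # decomposition of the count likelihood)
  mp[1:4, 1] <- init_mean
  Pp[1:4, 1:4, 1] <- init_cov
  for (t in 1:T) {
    yhat[t] <- inprod(H[], mp[1:4, t])
    S[t] <- inprod(H[], Pp[1:4, 1:4, t] %*% H[]) + sv2[t]
    for (i in 1:4) {
      PH[i, t] <- inprod(Pp[i, 1:4, t], H[])
      K[i, t] <- obs_flag[t] * PH[i, t] / S[t]
      mf[i, t] <- mp[i, t] + K[i, t] * (yfill[t] - yhat[t])
    }
    for (i in 1:4) {
      for (j in 1:4) {
        Pf[i, j, t] <- Pp[i, j, t] - K[i, t] * PH[j, t]
      }
    }
    Ntot[t] <- sum(mf[1:4, t])
    Nbpop[t] <- 2 * (mf[3, t] + mf[4, t])
  }
  for (t in 1:(T - 1)) {
    A[t, 1, 1] <- 0
    A[t, 1, 2] <- 0
    A[t, 1, 3] <- fec[t] / 2 * phi_j[t]
    A[t, 1, 4] <- A[t, 1, 3]
    A[t, 2, 1] <- phi_a[t] * (1 - alpha)
    A[t, 2, 2] <- 0
    A[t, 2, 3] <- 0
    A[t, 2, 4] <- 0
    A[t, 3, 1] <- phi_a[t] * alpha
    A[t, 3, 2] <- 0
    A[t, 3, 3] <- 0
    A[t, 3, 4] <- 0
    A[t, 4, 1] <- 0
    A[t, 4, 2] <- phi_a[t]
    A[t, 4, 3] <- phi_a[t]
    A[t, 4, 4] <- phi_a[t]
    m1r[t] <- max(mf[1, t], 0)
    m234r[t] <- max(mf[2, t] + mf[3, t] + mf[4, t], 0)
    Qm[t, 1, 1] <- max(fec[t] / 2 * phi_j[t] * (mf[3, t] + mf[4, t]), 0.000001)
    Qm[t, 1, 2] <- 0
    Qm[t, 1, 3] <- 0
    Qm[t, 1, 4] <- 0
    Qm[t, 2, 1] <- 0
    Qm[t, 2, 2] <- m1r[t] * A[t, 2, 1] * (1 - A[t, 2, 1])
    Qm[t, 2, 3] <- -m1r[t] * A[t, 2, 1] * A[t, 3, 1]
    Qm[t, 2, 4] <- 0
    Qm[t, 3, 1] <- 0
    Qm[t, 3, 2] <- Qm[t, 2, 3]
    Qm[t, 3, 3] <- m1r[t] * A[t, 3, 1] * (1 - A[t, 3, 1])
    Qm[t, 3, 4] <- 0
    Qm[t, 4, 1] <- 0
    Qm[t, 4, 2] <- 0
    Qm[t, 4, 3] <- 0
    Qm[t, 4, 4] <- m234r[t] * phi_a[t] * (1 - phi_a[t])
    mp[1:4, t + 1] <- A[t, 1:4, 1:4] %*% mf[1:4, t]
    Pp[1:4, 1:4, t + 1] <- A[t, 1:4, 1:4] %*% Pf[1:4, 1:4, t] %*% t(A[t, 1:4, 1:4]) + Qm[t, 1:4, 1:4]
  }
  for (k in 1:n_obs) {
    y_obs[k] ~ dnorm(yhat[obs_t[k]], 1 / S[obs_t[k]])
  }" else paste0("
  # latent stage-structured population (prebreeding census)
  ci1 ~ dcat(pinit1[]); n1[1] <- init_lo[1] - 1 + ci1
  ci2 ~ dcat(pinit2[]); n2[1] <- init_lo[2] - 1 + ci2
  ci3 ~ dcat(pinit3[]); n3[1] <- init_lo[3] - 1 + ci3
  ci4 ~ dcat(pinit4[]); n4[1] <- init_lo[4] - 1 + ci4
  for (t in 1:(T - 1)) {", state_proc, "
  }
  for (t in 1:T) {
    Ntot[t] <- n1[t] + n2[t] + n3[t] + n4[t]
    Nbpop[t] <- 2 * (n3[t] + n4[t])
  }

  # count likelihood (surveyed years only)
  for (k in 1:n_obs) {
    y_obs[k] ~ dnorm(Nbpop[obs_t[k]], tau_y[k])
  }")
  paste0("
model {
  # hyperpriors (Beta priors on the mean probabilities, Table-style)
  mean_phia ~ dbeta(pr_phia[1], pr_phia[2])
  mu_phia <- logit(mean_phia)
  mean_phij ~ dbeta(pr_phij[1], pr_phij[2])
  mu_phij <- logit(mean_phij)
  alpha ~ dbeta(pr_alpha[1], pr_alpha[2])
  mean_p ~ dbeta(pr_p[1], pr_p[2])
  mu_p <- logit(mean_p)
  mean_ns ~ dbeta(pr_ns[1], pr_ns[2])
  mu_ns <- logit(mean_ns)
  cs ~ dgamma(pr_cs[1], pr_cs[2])
  sigma_phia ~ dunif(pr_sigma[1], pr_sigma[2])
  sigma_phij ~ dunif(pr_sigma[1], pr_sigma[2])
  sigma_p ~ dunif(pr_sigma[1], pr_sigma[2])
  sigma_ns ~ dunif(pr_sigma[1], pr_sigma[2])", beta_priors, "

  # annual rates: logit-scale regression means with Normal year effects,
  # written in hierarchically centered form (the year-level logits are
  # drawn around the regression mean) so the hyperparameters and
  # regression coefficients decouple from the data likelihoods -- this
  # mixes orders of magnitude faster here than the uncentered form
  tau_phia <- pow(sigma_phia, -2)
  tau_phij <- pow(sigma_phij, -2)
  tau_p <- pow(sigma_p, -2)
  tau_ns <- pow(sigma_ns, -2)
  for (t in 1:(T - 1)) {
    lphi_a[t] ~ dnorm(mu_phia", cov_phia, ", tau_phia)
    phi_a[t] <- ilogit(lphi_a[t])
    lphi_j[t] ~ dnorm(mu_phij", cov_phij, ", tau_phij)
    phi_j[t] <- ilogit(lphi_j[t])
    lp[t] ~ dnorm(mu_p, tau_p)
    p[t] <- ilogit(lp[t])
    q[t] <- 1 - p[t]
  }
  for (t in 1:T) {
    lns[t] ~ dnorm(mu_ns", cov_ns, ", tau_ns)
    ns[t] <- ilogit(lns[t])
    fec[t] <- ns[t] * cs * ds
  }
", count_block, "

  # adult m-array (CJS multinomial cells)
  for (t in 1:(T - 1)) {
    pr_a[t, t] <- phi_a[t] * p[t]
    for (j in (t + 1):(T - 1)) {
      pr_a[t, j] <- prod(phi_a[t:j]) * prod(q[t:(j - 1)]) * p[j]
    }
    for (j in 1:(t - 1)) {
      pr_a[t, j] <- 0
    }
    pr_a[t, T] <- 1 - sum(pr_a[t, 1:(T - 1)])
    marr_a[t, 1:T] ~ dmulti(pr_a[t, 1:T], rel_a[t])
  }

  # duckling m-array: unobservable at age 1; breeds at 2 with alpha,
  # else certainly at 3 (rows for the last release occasion carry no
  # information and are dropped on the R side)
  for (t in 1:(T - 2)) {
    for (j in 1:t) {
      pr_d[t, j] <- 0
    }
    pr_d[t, t + 1] <- phi_j[t] * phi_a[t + 1] * alpha * p[t + 1]
    pr_d[t, T] <- 1 - sum(pr_d[t, 1:(T - 1)])
    marr_d[t, 1:T] ~ dmulti(pr_d[t, 1:T], rel_d[t])
  }
  for (t in 1:(T - 3)) {
    pr_d[t, t + 2] <- phi_j[t] * phi_a[t + 1] * (1 - alpha * p[t + 1]) * phi_a[t + 2] * p[t + 2]
    for (j in (t + 3):(T - 1)) {
      pr_d[t, j] <- phi_j[t] * phi_a[t + 1] * (1 - alpha * p[t + 1]) * prod(phi_a[(t + 2):j]) * prod(q[(t + 2):(j - 1)]) * p[j]
    }
  }

  # productivity likelihood
  for (t in 1:T) {
    succ[t] ~ dbin(ns[t], nn[t])
  }
  eggs_total ~ dpois(cs * n_clutches)
}")
}

jags_data <- function(data, covariates, priors, process = "marginal") {
  T <- length(data$years)
  marr_a <- build_marray(data$histories, "adult")
  marr_d <- build_marray(data$histories, "duckling")
  obs <- which(!is.na(data$counts$y))
  clutches <- unlist(data$nests$clutches)
  if (length(clutches) == 0)
    stop("no observed clutches; clutch size is not estimable")
  jd <- list(
    T = T, ds = data$ds,
    y_obs = data$counts$y[obs], obs_t = obs, n_obs = length(obs),
    marr_a = marr_a$m, rel_a = unname(marr_a$releases),
    marr_d = marr_d$m[seq_len(T - 2), , drop = FALSE],
    rel_d = unname(marr_d$releases[seq_len(T - 2)]),
    nn = data$nests$n_nests, succ = data$nests$n_success,
    eggs_total = sum(clutches), n_clutches = length(clutches),
    pr_phia = priors$phi_a, pr_phij = priors$phi_j,
    pr_alpha = priors$alpha, pr_p = priors$p, pr_ns = priors$ns,
    pr_cs = priors$cs, pr_sigma = priors$sigma,
    beta_tau = 1 / priors$beta_sd^2
  )
  if (process == "marginal") {
    sv2 <- data$counts$sigma_y^2
    sv2[-obs] <- mean(sv2[obs])
    jd$H <- c(0, 0, 2, 2)
    jd$init_mean <- vapply(priors$init, mean, numeric(1))
    jd$init_cov <- diag(vapply(priors$init, function(b)
      ((b[2] - b[1] + 1)^2 - 1) / 12, numeric(1)))
    jd$sv2 <- sv2
    jd$obs_flag <- as.numeric(!is.na(data$counts$y))
    jd$yfill <- ifelse(is.na(data$counts$y), 0, data$counts$y)
  } else {
    jd$tau_y <- 1 / data$counts$sigma_y[obs]^2
    jd$init_lo <- vapply(priors$init, `[`, numeric(1), 1)
    for (i in 1:4) {
      K <- priors$init[[i]][2] - priors$init[[i]][1] + 1
      jd[[paste0("pinit", i)]] <- rep(1 / K, K)
    }
  }
  if (covariates) {
    cov <- data$covariates
    if (is.null(cov)) stop("data bundle has no covariates")
    jd$ice_surv <- cov$ice_days[2:T]
    jd$ao_surv <- cov$ao[2:T]
    jd$ice_ns <- cov$ice_days
    jd$fox <- cov$fox
    jd$precip <- cov$precip
  } else {
    jd$beta_tau <- NULL
  }
  jd
}

#' Fit the integrated population model
#'
#' Joint Bayesian fit of the state-space count model, the multistate
#' capture-recapture m-array likelihood, and the productivity likelihoods,
#' with annual logit-scale random effects and (optionally) environmental
#' covariates on the demographic rates.  Sampling is by MCMC in JAGS
#' (Gibbs/slice updates, discrete latent states sampled directly).
#'
#' Defaults are scaled for routine use (3 chains, 3,000 kept draws per
#' chain); `paper_protocol = TRUE` switches to the long protocol of 3
#' chains x 900,000 iterations with an 800,000 burn-in thinned by 25
#' (12,000 kept draws).
#'
#' @param data An [ipm_data()] bundle.
#' @param covariates Fit the environmental-covariates model (`TRUE`) or
#'   the temporal-variation model (`FALSE`, all covariate terms removed).
#' @param process Latent-state process: `"marginal"` (the default: the
#'   stochastic stage process is moment-matched by a Gaussian and the
#'   latent stages integrated out analytically, see
#'   [count_marginal_loglik()]), `"stochastic"` (exact integer states,
#'   Poisson/binomial transitions, sampled directly -- the full-fidelity
#'   fallback, which needs paper-protocol-length chains to mix), or
#'   `"deterministic"`.
#' @param chains,n_adapt,n_burnin,n_iter,thin MCMC protocol; `n_iter`
#'   counts post-burn-in iterations before thinning.
#' @param paper_protocol Use the full published protocol (overrides the
#'   iteration settings).
#' @param seed Integer seed; chain RNGs are derived from it, so identical
#'   seeds give identical draws.
#' @param priors A prior set from [default_priors()].
#' @param quiet Suppress JAGS progress output.
#' @return An object of class `eider_ipm`: list with `samples` (a
#'   `coda::mcmc.list`), `data`, `config` (sampler metadata including the
#'   seed and latent-state mode), `rhat` (per-parameter Gelman-Rubin
#'   statistics), and `converged` (all R-hat <= 1.05).
#' @seealso [summary.eider_ipm()], [gof_freeman_tukey()],
#'   [gof_chisq_counts()], [demographic_correlations()]
#' @export
ipm_fit <- function(data, covariates = !is.null(data$covariates),
                    process = c("marginal", "stochastic", "deterministic"),
                    chains = 3, n_adapt = 1000, n_burnin = 2000,
                    n_iter = 3000, thin = 1, paper_protocol = FALSE,
                    seed = 1, priors = default_priors(), quiet = TRUE) {
  process <- match.arg(process)
  stopifnot(inherits(data, "ipm_data"))
  if (paper_protocol) {
    chains <- 3; n_adapt <- 10000; n_burnin <- 790000
    n_iter <- 100000; thin <- 25
  }
  jd <- jags_data(data, covariates, priors, process)
  model <- jags_model_string(covariates, process)
  inits <- lapply(seq_len(chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed * 1000 + ch)))
  monitors <- c("mean_phia", "mean_phij", "alpha", "mean_p", "mean_ns",
                "cs", "sigma_phia", "sigma_phij", "sigma_p", "sigma_ns",
                "phi_a", "phi_j", "ns", "p", "fec", "Ntot", "Nbpop")
  if (process == "marginal") monitors <- c(monitors, "yhat", "S")
  if (covariates)
    monitors <- c(monitors, "b_phia_lin", "b_phia_quad", "b_phij_ao",
                  "b_ns_lin", "b_ns_quad", "b_ns_fox", "b_ns_precip")
  t0 <- proc.time()[["elapsed"]]
  run <- function() {
    jm <- rjags::jags.model(textConnection(model), data = jd, inits = inits,
                            n.chains = chains, n.adapt = n_adapt,
                            quiet = quiet)
    if (n_burnin > 0) stats::update(jm, n_burnin,
                                    progress.bar = if (quiet) "none" else "text")
    list(jm = jm,
         samples = rjags::coda.samples(jm, monitors, n.iter = n_iter,
                                       thin = thin,
                                       progress.bar = if (quiet) "none" else "text"))
  }
  out <- if (quiet) suppressMessages(run()) else run()
  elapsed <- proc.time()[["elapsed"]] - t0
  rh <- rhat_all(out$samples)
  structure(list(
    samples = out$samples, data = data,
    config = list(covariates = covariates, process = process,
                  chains = chains, n_adapt = n_adapt, n_burnin = n_burnin,
                  n_iter = n_iter, thin = thin, seed = seed,
                  sampler = if (process == "marginal")
                    "JAGS (rjags); latent stages marginalized (Gaussian moment match)"
                  else "JAGS (rjags); discrete latent states sampled",
                  paper_protocol = paper_protocol, elapsed_sec = elapsed),
    rhat = rh,
    converged = if (chains < 2) NA else all(rh <= 1.05, na.rm = TRUE)
  ), class = "eider_ipm")
}

#' @export
print.eider_ipm <- function(x, ...) {
  cfg <- x$config
  cat("Integrated population model fit (", if (cfg$covariates)
    "environmental-covariates model" else "temporal-variation model",
    ")\n", sep = "")
  cat(sprintf("  %d years, %d chains x %d iterations (thin %d), %s latent process\n",
              length(x$data$years), cfg$chains, cfg$n_iter, cfg$thin, cfg$process))
  cat(sprintf("  sampler: %s; seed %s; %.1f s\n", cfg$sampler,
              format(cfg$seed), cfg$elapsed_sec))
  mr <- suppressWarnings(max(x$rhat, na.rm = TRUE))
  if (is.finite(mr))
    cat(sprintf("  max R-hat: %.3f (%s)\n", mr,
                if (isTRUE(x$converged)) "all <= 1.05" else "NOT converged"))
  else cat("  R-hat unavailable (single chain)\n")
  est <- coef(x)
  cat("  posterior means:\n")
  print(round(est, 3))
  invisible(x)
}

#' Extract posterior draws of a monitored quantity
#'
#' @param fit An `eider_ipm` fit.
#' @param name Monitor name, e.g. `"ns"` (annual vector) or `"alpha"`
#'   (scalar).
#' @return A draws x dimension matrix (columns in index order).
#' @export
posterior_matrix <- function(fit, name) {
  mat <- as.matrix(fit$samples)
  cols <- colnames(mat)
  exact <- cols == name
  if (any(exact)) return(mat[, exact, drop = FALSE])
  idx <- grep(paste0("^", name, "\\["), cols)
  if (!length(idx)) stop("no monitored quantity called ", name)
  sub <- mat[, idx, drop = FALSE]
  ord <- order(as.integer(sub("^.*\\[(\\d+)\\]$", "\\1", colnames(sub))))
  sub[, ord, drop = FALSE]
}

#' @export
coef.eider_ipm <- function(object, ...) {
  scalars <- c("mean_phia", "mean_phij", "alpha", "mean_p", "mean_ns", "cs",
               "sigma_phia", "sigma_phij", "sigma_p", "sigma_ns",
               if (object$config$covariates)
                 c("b_phia_lin", "b_phia_quad", "b_phij_ao", "b_ns_lin",
                   "b_ns_quad", "b_ns_fox", "b_ns_precip"))
  mat <- as.matrix(object$samples)
  colMeans(mat[, intersect(scalars, colnames(mat)), drop = FALSE])
}
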