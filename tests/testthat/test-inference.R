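# A minimal hand-built fit object lets the summary/GoF/correlation code
# be tested without running MCMC.
fake_fit <- function(draws_list, data = NULL, covariates = FALSE) {
  samples <- coda::mcmc.list(lapply(draws_list, coda::mcmc))
  structure(list(samples = samples, data = data,
                 config = list(covariates = covariates, chains = length(draws_list)),
                 rhat = eiderIPM:::rhat_all(samples)),
            class = "eider_ipm")
}

test_that("R-hat matches the hand formula and flags divergence", {
  # two chains of five draws, worked by hand
  c1 <- c(1, 2, 3, 4, 5); c2 <- c(2, 3, 4, 5, 6)
  W <- (var(c1) + var(c2)) / 2            # 2.5
  B <- 5 * var(c(mean(c1), mean(c2)))     # 2.5
  hand <- sqrt((4 / 5 * W + B / 5) / W)
  expect_equal(W, 2.5)
  expect_equal(B, 2.5)
  expect_equal(rhat(cbind(c1, c2)), hand)

  set.seed(102)
  x <- matrix(rnorm(4000), 1000, 4)
  expect_equal(rhat(x), 1, tolerance = 0.01)
  expect_equal(rhat(cbind(c(5, 5, 5), c(5, 5, 5))), 1)

  disjoint <- cbind(rnorm(200, 0, 0.1), rnorm(200, 10, 0.1))
  expect_gt(rhat(disjoint), 1.05)
  expect_error(rhat(matrix(1:5)), "two chains")

  # independent cross-check against coda's implementation
  m <- coda::mcmc.list(coda::mcmc(matrix(rnorm(500), ncol = 1)),
                       coda::mcmc(matrix(rnorm(500, 0.2), ncol = 1)))
  psrf <- unname(coda::gelman.diag(m, autoburnin = FALSE)$psrf[1, 1])
  ours <- unname(rhat(sapply(m, as.numeric)))
  expect_equal(ours, psrf, tolerance = 0.02)
})

test_that("variance explained reproduces the closed-form ratios", {
  expect_equal(variance_explained(0.71, 0.59), 0.169, tolerance = 1e-3)
  expect_equal(variance_explained(1.13, 0.64), 0.434, tolerance = 1e-3)
  expect_equal(variance_explained(0.5, 0.5), 0)
  expect_warning(v <- variance_explained(0.5, 0.6), "negative")
  expect_lt(v, 0)
  expect_error(variance_explained(0, 1), "positive")
})

test_that("Freeman-Tukey discrepancy and p-value behave at the extremes", {
  nests <- data.frame(year = 2001, n_nests = 16, n_success = 9)
  # expected successes 4 => D_obs = (3 - 2)^2 = 1
  ns_draws <- matrix(0.25, nrow = 50, ncol = 1)
  g <- gof_freeman_tukey(ns_draws, nests, seed = 1)
  expect_equal(unique(g$D_obs), 1)

  # observed equals expected in every year: D_obs = 0, p-value ~ 1
  nests2 <- data.frame(year = 2001:2003, n_nests = c(16, 25, 36),
                       n_success = c(8, 10, 18))
  ns2 <- matrix(rep(c(0.5, 0.4, 0.5), each = 200), nrow = 200)
  g2 <- gof_freeman_tukey(ns2, nests2, seed = 2)
  expect_equal(unique(g2$D_obs), 0)
  expect_gt(g2$p_value, 0.95)
  expect_true(g2$p_value >= 0 && g2$p_value <= 1)
})

test_that("count chi-square p-value is 1 under a perfect fit and excludes missing years", {
  counts <- data.frame(year = 2001:2005, y = c(100, 110, NA, 130, 140),
                       sigma_y = 10)
  Nb <- matrix(rep(c(100, 110, 999, 130, 140), each = 30), nrow = 30)
  colnames(Nb) <- paste0("Nbpop[", 1:5, "]")
  fit <- fake_fit(list(Nb))
  g <- gof_chisq_counts(fit, counts, seed = 3)
  expect_equal(unique(g$X2_obs), 0)  # missing year excluded despite Nb = 999
  expect_equal(g$p_value, 1)
})

test_that("demographic correlations recover exact and degenerate cases", {
  T <- 6; D <- 40
  set.seed(104)
  Ntot <- matrix(rep(exp(seq(0, 1, length.out = T)) * 1000, each = D), D)
  lam <- Ntot[1, -1] / Ntot[1, -T]
  mk <- function(v) {
    m <- matrix(rep(v, each = D), D)
    m
  }
  draws <- cbind(mk(Ntot[1, ]), mk(lam), mk(lam), mk(lam + 0.01), mk(lam))
  colnames(draws) <- c(paste0("Ntot[", 1:T, "]"), paste0("phi_a[", 1:(T-1), "]"),
                       paste0("phi_j[", 1:(T-1), "]"), paste0("ns[", 1:(T-1), "]"),
                       paste0("fec[", 1:(T-1), "]"))
  # pad ns/fec to T columns (last year unused by the correlation)
  draws <- cbind(draws, `ns[6]` = 0.5, `fec[6]` = 1)
  fit <- fake_fit(list(draws))
  res <- demographic_correlations(fit)
  expect_equal(res$mean[res$rate == "phi_a"], 1, tolerance = 1e-12)
  expect_equal(res$p_gt0[res$rate == "phi_a"], 1)

  # constant rate series: undefined correlation, draws skipped and counted
  draws2 <- draws
  draws2[, paste0("phi_j[", 1:(T-1), "]")] <- 0.3
  fit2 <- fake_fit(list(draws2))
  expect_message(res2 <- demographic_correlations(fit2), "skipped")
  expect_equal(res2$n_skipped[res2$rate == "phi_j"], D)
  expect_error(demographic_correlations(fake_fit(list(cbind(`Ntot[1]` = 1:5,
                                                            `Ntot[2]` = 2:6)))),
               "three years")
})

test_that("posterior mode finds the density peak", {
  set.seed(105)
  x <- c(rnorm(2000, 0, 0.3), rnorm(500, 3, 0.3))
  expect_equal(posterior_mode(x), 0, tolerance = 0.15)
  expect_equal(posterior_mode(rep(2.5, 10)), 2.5)
})

test_that("summary reports quantile CrIs that match a sorting oracle", {
  set.seed(106)
  D <- 400
  draws <- cbind(mean_phia = rbeta(D, 8, 2), mean_phij = rbeta(D, 3, 7),
                 alpha = rbeta(D, 4, 6), mean_p = rbeta(D, 5, 5),
                 mean_ns = rbeta(D, 6, 3), cs = rgamma(D, 20, 5),
                 sigma_phia = runif(D), sigma_phij = runif(D),
                 sigma_p = runif(D), sigma_ns = runif(D),
                 `Ntot[1]` = rnorm(D, 1000, 5), `Ntot[2]` = rnorm(D, 1100, 5),
                 `Ntot[3]` = rnorm(D, 1200, 5),
                 `Nbpop[1]` = rnorm(D, 900, 5), `Nbpop[2]` = rnorm(D, 950, 5),
                 `Nbpop[3]` = rnorm(D, 1000, 5))
  fit <- fake_fit(list(draws[1:200, ], draws[201:400, ]))
  s <- summary(fit)
  # every prior-set parameter is reported
  expect_true(all(c("mean_phia", "mean_phij", "alpha", "mean_p", "mean_ns",
                    "cs", "sigma_phia", "sigma_phij", "sigma_p", "sigma_ns",
                    "geo_lambda_nbpop", "geo_lambda_ntot") %in% s$parameter))
  # sorting oracle for the 95% CrI of mean_phia
  srt <- sort(draws[, "mean_phia"])
  expect_equal(s$lower[s$parameter == "mean_phia"],
               unname(quantile(srt, 0.025)), tolerance = 1e-12)
  expect_equal(s$upper[s$parameter == "mean_phia"],
               unname(quantile(srt, 0.975)), tolerance = 1e-12)
  expect_true(all(s$lower <= s$upper))

  # degenerate single-value draws: zero-width interval at the value
  dg <- draws; dg[, "cs"] <- 4.297
  fitd <- fake_fit(list(dg))
  sd_ <- summary(fitd)
  expect_equal(sd_$mean[sd_$parameter == "cs"], 4.297)
  expect_equal(sd_$lower[sd_$parameter == "cs"],
               sd_$upper[sd_$parameter == "cs"])

  # per-draw geometric lambda identity: (N_T / N_1)^(1/(T-1))
  gl <- apply(draws[, paste0("Ntot[", 1:3, "]")], 1,
              function(v) (v[3] / v[1])^(1 / 2))
  expect_equal(s$mean[s$parameter == "geo_lambda_ntot"], mean(gl),
               tolerance = 1e-10)
})
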