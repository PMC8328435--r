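# Independent oracles used across the suite.  These deliberately take a
# different computational route from the package code they check.

# Exact log-likelihood of a single capture history by a forward sum over
# the hidden state space {just-released duckling, 1-year-old, 2-year-old
# non-breeder, breeder, dead}.  Detection is possible only while breeding.
# phi_j / phi_a are interval-indexed (t -> t+1), p_occ occasion-indexed.
oracle_history_loglik <- function(det, first, cohort, phi_j, phi_a, alpha, p_occ) {
  T <- length(det)
  f <- c(R = 0, A1 = 0, N2 = 0, B = 0, D = 0)
  f[if (cohort == "adult") "B" else "R"] <- 1
  if (first < T) for (m in first:(T - 1)) {
    g <- c(R = 0, A1 = 0, N2 = 0, B = 0, D = 0)
    g["A1"] <- f[["R"]] * phi_j[m]
    g["N2"] <- f[["A1"]] * phi_a[m] * (1 - alpha)
    g["B"] <- (f[["A1"]] * alpha + f[["N2"]] + f[["B"]]) * phi_a[m]
    g["D"] <- f[["D"]] + f[["R"]] * (1 - phi_j[m]) +
      (f[["A1"]] + f[["N2"]] + f[["B"]]) * (1 - phi_a[m])
    if (det[m + 1] == 1) {
      g[c("R", "A1", "N2", "D")] <- 0
      g["B"] <- g[["B"]] * p_occ[m + 1]
    } else {
      g["B"] <- g[["B"]] * (1 - p_occ[m + 1])
    }
    f <- g
  }
  log(sum(f))
}

oracle_set_loglik <- function(histories, phi_j, phi_a, alpha, p_occ) {
  years <- attr(histories, "years")
  det <- as.matrix(histories[as.character(years)])
  sum(vapply(seq_len(nrow(histories)), function(i) {
    first <- match(histories$first_year[i], years)
    oracle_history_loglik(det[i, ], first, histories$cohort[i],
                          phi_j, phi_a, alpha, p_occ)
  }, numeric(1)))
}

# Random valid capture histories (not drawn from the model on purpose:
# the m-array/product-of-histories identity holds for arbitrary data).
random_histories <- function(n, T, p_detect = 0.35) {
  years <- 2000 + seq_len(T)
  rows <- lapply(seq_len(n), function(i) {
    cohort <- sample(c("adult", "duckling"), 1)
    first <- sample(seq_len(T - 1), 1)
    det <- integer(T)
    det[first] <- 1L
    later <- seq_len(T)[seq_len(T) > first]
    if (cohort == "duckling") later <- setdiff(later, first + 1)
    det[later] <- stats::rbinom(length(later), 1, p_detect)
    data.frame(id = paste0("i", i), cohort = cohort, first_year = years[first],
               t(det))
  })
  df <- do.call(rbind, rows)
  names(df) <- c("id", "cohort", "first_year", years)
  read_capture_histories(df)
}

# Convenience: a small synthetic bundle at reduced size for smoke fits.
small_bundle <- function(T = 10, seed = 11, ...) {
  simulate_ipm_data(ipm_truth(T = T, ducklings_per_year = 20,
                              adults_per_year = 20, nests_per_year = 40,
                              missing_count_year = min(5, T - 1), ...),
                    seed = seed)
}
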