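make_histories <- function(dets, cohorts = NULL) {
  # dets: character vector like "1011"; all released at their first 1
  T <- nchar(dets[1])
  years <- 2000 + seq_len(T)
  if (is.null(cohorts)) cohorts <- rep("adult", length(dets))
  rows <- lapply(seq_along(dets), function(i) {
    det <- as.integer(strsplit(dets[i], "")[[1]])
    data.frame(id = paste0("h", i), cohort = cohorts[i],
               first_year = years[which(det == 1)[1]], t(det))
  })
  df <- do.call(rbind, rows)
  names(df) <- c("id", "cohort", "first_year", years)
  read_capture_histories(df)
}

test_that("capture-history validation enforces observability rules", {
  h <- make_histories(c("1001"))
  expect_s3_class(h, "capture_histories")
  expect_error(make_histories("1100", "duckling"), "unobservable")
  # detection before first_year
  df <- as.data.frame(make_histories("0110"))
  df$first_year <- 2003
  expect_error(read_capture_histories(df), "before first_year")
  df$first_year <- 2004
  expect_error(read_capture_histories(df), "no detection recorded")
  empty <- data.frame(id = character(), cohort = character(),
                      first_year = integer(),
                      `2001` = integer(), `2002` = integer(),
                      check.names = FALSE)
  expect_warning(e <- read_capture_histories(empty), "empty")
  expect_equal(nrow(e), 0)
})

test_that("m-array matches hand enumeration of three adult histories", {
  h <- make_histories(c("1011", "1100", "1000"))
  ma <- build_marray(h, "adult")
  expect_equal(unname(ma$releases), c(3, 1, 1))
  m <- unname(ma$m)
  # columns: recapture occasions 2,3,4, never
  expect_equal(m[1, ], c(1, 1, 0, 1))  # m12=1, m13=1, never1=1
  expect_equal(m[2, ], c(0, 0, 0, 1))  # the re-release of "1100", never again
  expect_equal(m[3, ], c(0, 0, 1, 0))  # m34 from "1011"
})

test_that("one never-recaptured history puts all mass in never-seen", {
  ma <- build_marray(make_histories("1000"), "adult")
  expect_equal(unname(ma$m[1, ]), c(0, 0, 0, 1))
})

test_that("duckling releases recruit into the adult m-array after first recapture", {
  # duckling released occ 1, recaptured occ 3 (age 2), again occ 5
  h <- make_histories(c("10101"), "duckling")
  md <- build_marray(h, "duckling")
  ma <- build_marray(h, "adult")
  expect_equal(unname(md$m[1, ]), c(0, 1, 0, 0, 0))   # first recapture occ 3
  expect_equal(unname(ma$m[3, ]), c(0, 0, 0, 1, 0))   # re-release occ 3 -> occ 5
  expect_equal(sum(ma$m[c(1, 2, 4), ]), 0)
})

test_that("m-array row sums reproduce release counts on random histories", {
  set.seed(42)
  for (rep in 1:10) {
    T <- sample(4:8, 1)
    h <- random_histories(sample(5:25, 1), T)
    det <- as.matrix(as.data.frame(h)[, -(1:3)])
    for (cohort in c("adult", "duckling")) {
      ma <- build_marray(h, cohort)
      expect_equal(ma$releases, rowSums(ma$m))
    }
    # every detection event is accounted for exactly once across both
    # arrays (releases in the final occasion drop out)
    ma <- build_marray(h, "adult"); md <- build_marray(h, "duckling")
    n_recaptures <- sum(det) - nrow(h)
    expect_equal(sum(ma$m[, seq_len(T - 1)]) + sum(md$m[, seq_len(T - 1)]),
                 n_recaptures)
  }
})

test_that("adult cell probabilities match the CJS path products", {
  p <- rep(0.5, 5); phi <- rep(0.8, 4)
  pr <- adult_cell_probabilities(phi, p)
  expect_equal(pr[1, 1], 0.8 * 0.5)          # next occasion: 0.40
  expect_equal(pr[1, 2], 0.8 * 0.5 * 0.8 * 0.5)  # two occasions out: 0.16
  expect_equal(rowSums(pr), rep(1, 4))

  pr0 <- adult_cell_probabilities(phi, rep(0, 5))
  expect_equal(unname(pr0[, 5]), rep(1, 4))
  expect_equal(sum(pr0[, 1:4]), 0)

  pr1 <- adult_cell_probabilities(rep(1, 4), rep(1, 5))
  expect_equal(pr1[1, 1], 1)
  expect_equal(sum(pr1[1, 2:5]), 0)
  expect_error(adult_cell_probabilities(phi, p[1:3]), "length")
})

test_that("duckling cell probabilities match path enumeration", {
  p <- rep(0.5, 6); phi_j <- rep(0.5, 5); phi_a <- rep(0.8, 5)
  pr <- duckling_cell_probabilities(phi_j, phi_a, 0.5, p)
  expect_equal(pr[1, 1], 0)                 # age 1 unobservable
  expect_equal(pr[1, 2], 0.10)              # recaptured as 2-year-old breeder
  expect_equal(pr[1, 3], 0.12)              # first seen at age 3
  expect_equal(pr[1, 4], 0.048)
  expect_equal(rowSums(pr), rep(1, 5))

  # alpha = 1 collapses to a delayed CJS: cell(+2) = phi_j phi_a p
  pr_a1 <- duckling_cell_probabilities(phi_j, phi_a, 1, p)
  expect_equal(pr_a1[1, 2], 0.5 * 0.8 * 0.5)
  # and the age-3 cell is pure breeder-undetected continuation
  expect_equal(pr_a1[1, 3], 0.5 * 0.8 * (1 - 0.5) * 0.8 * 0.5)

  pr_p0 <- duckling_cell_probabilities(phi_j, phi_a, 0.5, rep(0, 6))
  expect_equal(unname(pr_p0[, 6]), rep(1, 5))
})

test_that("m-array likelihood equals the per-history forward-sum oracle", {
  set.seed(99)
  for (rep in 1:10) {
    T <- sample(4:6, 1)
    h <- random_histories(sample(4:10, 1), T)
    phi_j <- runif(T - 1, 0.1, 0.9)
    phi_a <- runif(T - 1, 0.3, 0.95)
    alpha <- runif(1, 0.1, 0.9)
    p_occ <- c(NA, runif(T - 1, 0.1, 0.9))
    p_use <- replace(p_occ, 1, 0.5)
    ll <- cmr_loglik(build_marray(h, "adult"),
                     adult_cell_probabilities(phi_a, p_use)) +
      cmr_loglik(build_marray(h, "duckling"),
                 duckling_cell_probabilities(phi_j, phi_a, alpha, p_use))
    oracle <- oracle_set_loglik(h, phi_j, phi_a, alpha, p_occ)
    expect_equal(ll, oracle, tolerance = 1e-10)
  }
})

test_that("degenerate m-array likelihoods", {
  h <- make_histories(c("1000", "1000"))
  ma <- build_marray(h, "adult")
  # p = 0 everywhere: all-never has probability one
  pr <- adult_cell_probabilities(rep(0.7, 3), rep(0, 4))
  expect_equal(cmr_loglik(ma, pr), 0)
  # empty m-array
  ma0 <- ma; ma0$m[] <- 0L; ma0$releases[] <- 0
  expect_equal(cmr_loglik(ma0, pr), 0)
  # positive count in a zero-probability cell
  prz <- pr; prz[1, 4] <- 0
  expect_warning(ll <- cmr_loglik(ma, prz), "zero-probability")
  expect_identical(ll, -Inf)
})
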