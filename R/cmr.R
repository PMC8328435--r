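#' Read and validate capture histories
#'
#' Capture histories of female eiders marked either as 30-day-old
#' ducklings or as breeding adults.  Detection is conditional on breeding:
#' 1-year-olds (and non-breeding 2-year-olds) are unobservable, so a
#' duckling-marked bird can never be detected one year after release, and
#' no bird can be detected before its release year.  Violations are
#' rejected with row-numbered errors.
#'
#' @param x A CSV path or data.frame with columns `id`, `cohort`
#'   (`"duckling"` or `"adult"`), `first_year`, and one 0/1 column per
#'   study year (headers are the calendar years).
#' @return An object of class `capture_histories`: the validated
#'   data.frame with a `years` attribute (ordered study years).
#' @export
read_capture_histories <- function(x) {
  df <- if (is.character(x)) utils::read.csv(x, check.names = FALSE) else as.data.frame(x, check.names = FALSE)
  req <- c("id", "cohort", "first_year")
  if (!all(req %in% names(df)))
    stop("capture-history table must have columns id, cohort, first_year")
  yc <- setdiff(names(df), req)
  years <- suppressWarnings(as.integer(sub("^[Xy]", "", yc)))
  if (any(is.na(years)))
    stop("detection columns must be named by calendar year; offending: ",
         paste(yc[is.na(years)], collapse = ", "))
  o <- order(years)
  years <- years[o]
  yc <- yc[o]
  if (nrow(df) == 0) {
    warning("empty capture-history table")
    out <- df[c(req, yc)]
    names(out) <- c(req, as.character(years))
    return(structure(out, years = years, class = c("capture_histories", "data.frame")))
  }
  det <- as.matrix(df[yc])
  if (!all(det %in% c(0L, 1L)))
    stop("detection entries must be 0 or 1")
  bad_cohort <- !df$cohort %in% c("duckling", "adult")
  if (any(bad_cohort))
    stop("row ", which(bad_cohort)[1], ": cohort must be 'duckling' or 'adult'")
  fi <- match(df$first_year, years)
  if (anyNA(fi))
    stop("row ", which(is.na(fi))[1], ": first_year outside the study years")
  for (i in seq_len(nrow(df))) {
    if (det[i, fi[i]] != 1)
      stop("row ", i, ": no detection recorded in first_year ", df$first_year[i])
    if (fi[i] > 1 && any(det[i, seq_len(fi[i] - 1)] == 1))
      stop("row ", i, ": detection before first_year ", df$first_year[i])
    if (df$cohort[i] == "duckling" && fi[i] < length(years) && det[i, fi[i] + 1] == 1)
      stop("row ", i, ": duckling-marked bird detected one year after release; ",
           "1-year-olds are unobservable")
  }
  out <- df[c(req, yc)]
  names(out) <- c(req, as.character(years))
  structure(out, years = years, class = c("capture_histories", "data.frame"))
}

#' Build an m-array from capture histories
#'
#' Tabulates releases and first recaptures by occasion.  Every detection
#' after a release contributes one `m[t, j]` cell (release occasion `t`,
#' first recapture occasion `j`), and the recaptured bird is re-released
#' into row `j`.  Duckling-marked birds contribute their initial release
#' to the duckling array; after first recapture they have recruited, so
#' all their subsequent releases enter the adult array.  Releases in the
#' final occasion carry no information and are dropped.
#'
#' @param histories A [read_capture_histories()] object.
#' @param cohort `"adult"` or `"duckling"`: which array to return.
#' @return A list with `m` (matrix, rows = release occasions `1:(T-1)`,
#'   columns = first-recapture occasions `2:T` plus `"never"`) and
#'   `releases` (row sums).
#' @export
build_marray <- function(histories, cohort = c("adult", "duckling")) {
  cohort <- match.arg(cohort)
  stopifnot(inherits(histories, "capture_histories"))
  years <- attr(histories, "years")
  T <- length(years)
  m <- matrix(0L, T - 1, T,
              dimnames = list(release = years[-T],
                              recapture = c(years[-1], "never")))
  det <- as.matrix(histories[as.character(years)])
  add_chain <- function(m, occs, start) {
    # occs: detection occasions from 'start' onwards; chain re-releases
    r <- start
    later <- occs[occs > r]
    while (length(later)) {
      j <- later[1]
      m[r, j - 1] <- m[r, j - 1] + 1L
      r <- j
      later <- later[later > r]
    }
    if (r < T) m[r, T] <- m[r, T] + 1L  # never seen again
    m
  }
  for (i in seq_len(nrow(histories))) {
    occs <- which(det[i, ] == 1)
    first <- occs[1]
    if (histories$cohort[i] == "duckling") {
      if (cohort == "duckling") {
        if (first < T) {
          recap <- occs[occs > first]
          if (length(recap)) {
            m[first, recap[1] - 1] <- m[first, recap[1] - 1] + 1L
          } else {
            m[first, T] <- m[first, T] + 1L
          }
        }
      } else {
        recap <- occs[occs > first]
        if (length(recap) && recap[1] < T) m <- add_chain(m, occs, recap[1])
      }
    } else if (cohort == "adult") {
      if (first < T) m <- add_chain(m, occs, first)
    }
  }
  list(m = m, releases = rowSums(m), cohort = cohort)
}

#' First-recapture cell probabilities for adult-marked releases
#'
#' Standard Cormack-Jolly-Seber multinomial cells: a bird released at
#' occasion `t` is first recaptured at occasion `j` with probability
#' `prod(phi_a[t:(j-1)]) * prod(1 - p[(t+1):(j-1)]) * p[j]`.
#'
#' @param phi_a Survival probabilities per interval (length `T - 1`).
#' @param p Recapture probabilities per occasion (length `T`; `p[1]` is
#'   never used).
#' @return A `(T-1) x T` matrix: columns are first-recapture occasions
#'   `2:T` plus a final `"never"` column; each row sums to 1.
#' @export
adult_cell_probabilities <- function(phi_a, p) {
  T <- length(p)
  if (length(phi_a) != T - 1)
    stop("phi_a must have length(p) - 1 elements")
  check_prob(c(phi_a, p[-1]))
  pr <- matrix(0, T - 1, T)
  q <- 1 - p
  for (t in seq_len(T - 1)) {
    surv <- phi_a[t]
    pr[t, t] <- surv * p[t + 1]              # column t <-> occasion t + 1
    if (t < T - 1) for (j in (t + 1):(T - 1)) {
      surv <- surv * q[j] * phi_a[j]
      pr[t, j] <- surv * p[j + 1]
    }
    pr[t, T] <- 1 - sum(pr[t, seq_len(T - 1)])
  }
  pr
}

#' First-recapture cell probabilities for duckling-marked releases
#'
#' Multistate CJS cells with unobservable pre-recruit states.  A duckling
#' released at occasion `t` survives its first year with `phi_j[t]` and
#' its second with `phi_a[t+1]`; at age 2 it breeds (and becomes
#' detectable) with probability `alpha`, otherwise it is an unobservable
#' non-breeder that breeds at age 3.  Detection one year after release is
#' structurally impossible.  Both pathways share the recapture
#' probabilities `p` (detectability of 2-year-old and older breeders is
#' assumed equal).
#'
#' @param phi_j First-year survival per interval (length `T - 1`).
#' @param phi_a Adult survival per interval (length `T - 1`).
#' @param alpha Breeding probability of 2-year-olds (scalar).
#' @param p Recapture probabilities per occasion (length `T`).
#' @return A `(T-1) x T` matrix as in [adult_cell_probabilities()].
#' @export
duckling_cell_probabilities <- function(phi_j, phi_a, alpha, p) {
  T <- length(p)
  if (length(phi_j) != T - 1 || length(phi_a) != T - 1)
    stop("phi_j and phi_a must have length(p) - 1 elements")
  check_prob(c(phi_j, phi_a, alpha, p[-1]))
  pr <- matrix(0, T - 1, T)
  q <- 1 - p
  for (t in seq_len(T - 1)) {
    if (t + 2 <= T)                          # recaptured as 2-year-old breeder
      pr[t, t + 1] <- phi_j[t] * phi_a[t + 1] * alpha * p[t + 2]
    if (t + 3 <= T) {
      # alive at t+2, not detected there (bred undetected or did not breed),
      # then breeds for sure at age 3
      base <- phi_j[t] * phi_a[t + 1] * (1 - alpha * p[t + 2]) * phi_a[t + 2]
      pr[t, t + 2] <- base * p[t + 3]
      if (t + 4 <= T) for (j in (t + 3):(T - 1)) {
        base <- base * q[j] * phi_a[j]
        pr[t, j] <- base * p[j + 1]
      }
    }
    pr[t, T] <- 1 - sum(pr[t, seq_len(T - 1)])
  }
  pr
}

check_prob <- function(x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("probabilities must lie in [0, 1]")
  invisible(x)
}

#' Multinomial log-likelihood of an m-array
#'
#' Sum over release rows of the multinomial log-likelihood kernel of the
#' first-recapture counts (including the never-seen-again cell) given the
#' release total: `sum(m * log(pr))`.  The multinomial coefficient -- a
#' constant in the parameters -- is omitted, so the value equals the log
#' of the product of the individual capture-history probabilities
#' exactly.  Additive over cohorts: call once per m-array and sum.
#'
#' @param marr A [build_marray()] result (or a list with `m` and
#'   `releases`).
#' @param cellprobs Matrix of cell probabilities matching `marr$m`,
#'   e.g. from [adult_cell_probabilities()].
#' @return The log-likelihood; `-Inf` (with a warning) if any cell with a
#'   positive count has probability zero.
#' @export
cmr_loglik <- function(marr, cellprobs) {
  m <- marr$m
  if (!all(dim(m) == dim(cellprobs)))
    stop("cell-probability matrix does not match the m-array dimensions")
  pos <- m > 0
  if (any(pos & cellprobs <= 0)) {
    bad <- which(pos & cellprobs <= 0, arr.ind = TRUE)[1, 1]
    warning("positive count in a zero-probability cell (release row ", bad, ")")
    return(-Inf)
  }
  sum(m[pos] * log(cellprobs[pos]))
}
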