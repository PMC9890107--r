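#' Chance-level reference distribution of participant success rates
#'
#' Simulates the "expected distribution" the observed success-rate
#' histogram is compared against: each simulated participant completes
#' `trials` trials at a homogeneous chance `p`, so rates live on the grid
#' {0, 1/trials, ..., 1}. The registered reference uses one million
#' simulated participants of 18 trials at 50%.
#'
#' @param n_participants number of simulated participants.
#' @param trials trials per participant.
#' @param p homogeneous success chance.
#' @return numeric vector of success rates, attribute `source =
#'   "simulated_null"`.
#' @export
null_rate_reference <- function(n_participants = 1e6, trials = 18L, p = 0.5) {
  stopifnot(n_participants >= 1, trials >= 1)
  structure(stats::rbinom(n_participants, trials, p) / trials,
            source = "simulated_null")
}

#' Earth mover's distance between two empirical distributions
#'
#' One-dimensional Wasserstein-1 distance between the empirical
#' distributions of two samples, computed as the integral of the absolute
#' difference of the empirical CDFs (handles unequal sample sizes).
#' Symmetric; zero iff the empirical distributions coincide.
#'
#' @param x,y nonempty numeric samples.
#' @return nonnegative scalar in the units of the samples.
#' @export
earth_movers_distance <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty", call. = FALSE)
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  z <- sort(unique(c(x, y)))
  if (length(z) == 1) return(0)
  fx <- stats::ecdf(x)(z[-length(z)])
  fy <- stats::ecdf(y)(z[-length(z)])
  sum(abs(fx - fy) * diff(z))
}

#' Odd-even split-half correlation of participant performance
#'
#' Splits each complete participant's erotic trials by within-participant
#' order (1st, 3rd, ... versus 2nd, 4th, ...), computes the success rate
#' in each half, and correlates the halves across participants. Stable
#' above-chance (or below-chance) individuals would show up as a positive
#' correlation; independent Bernoulli trials give r near 0.
#'
#' @param table confirmatory-filtered [trial_table()].
#' @param required_trials trials a participant must have to enter (18).
#' @param conf_level level of the Fisher-z confidence interval.
#' @return list with `r`, `ci_lo`, `ci_hi`, `n_participants`.
#' @export
odd_even_split_correlation <- function(table, required_trials = 18L,
                                       conf_level = 0.95) {
  stopifnot(inherits(table, "trial_table"))
  n_i <- table(table$participant_id)
  complete <- names(n_i)[n_i == required_trials]
  if (length(complete) < 3) {
    stop("need at least 3 participants with all ", required_trials,
         " erotic trials", call. = FALSE)
  }
  sub <- table[table$participant_id %in% complete, , drop = FALSE]
  # within-participant order is deposit order (table invariant)
  idx <- stats::ave(seq_len(nrow(sub)), sub$participant_id, FUN = seq_along)
  odd <- tapply(sub$success[idx %% 2 == 1], sub$participant_id[idx %% 2 == 1], mean)
  even <- tapply(sub$success[idx %% 2 == 0], sub$participant_id[idx %% 2 == 0], mean)
  even <- even[names(odd)]
  r <- stats::cor(as.numeric(odd), as.numeric(even))
  m <- length(odd)
  z <- atanh(r)
  half <- stats::qnorm(1 - (1 - conf_level) / 2) / sqrt(m - 3)
  list(r = r, ci_lo = tanh(z - half), ci_hi = tanh(z + half),
       n_participants = m)
}
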