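#' Beta priors truncated to the above-chance interval
#'
#' The one-sided alternative model M1 ("success chance above 50%") is given a
#' beta prior on the success probability, restricted and renormalized on
#' (0.5, 1). Three named priors are in routine use:
#'
#' * `"uniform"`: Beta(1, 1) — flat on (0.5, 1), density 2.
#' * `"buj"`: Beta(7, 7) — the knowledge-based Bem--Utts--Johnson prior,
#'   holding roughly 90% of its truncated mass below the probability
#'   equivalent of a Cohen's d of 0.5.
#' * `"replication"`: Beta(successes + 1, failures + 1) built from the
#'   counts of an original experiment; defaults 828 successes / 732
#'   failures (53.1% of 1560 trials), i.e. Beta(829, 733).
#'
#' @param label one of `"uniform"`, `"buj"`, `"replication"`, `"custom"`.
#' @param successes,failures counts seeding the replication prior
#'   (ignored for other labels).
#' @param a,b shape parameters for a `"custom"` prior.
#' @return an object of class `trunc_beta_prior` with fields `a`, `b`,
#'   `lower` (always 0.5) and `label`.
#' @examples
#' make_prior("buj")
#' make_prior("replication", successes = 828, failures = 732)
#' @export
make_prior <- function(label = c("uniform", "buj", "replication", "custom"),
                       successes = 828L, failures = 732L,
                       a = NULL, b = NULL) {
  label <- match.arg(label)
  shapes <- switch(label,
    uniform     = c(1, 1),
    buj         = c(7, 7),
    replication = c(successes + 1, failures + 1),
    custom      = c(a, b)
  )
  if (length(shapes) != 2 || any(!is.finite(shapes)) || any(shapes <= 0)) {
    stop("prior shapes must be positive and finite", call. = FALSE)
  }
  structure(
    list(a = shapes[[1]], b = shapes[[2]], lower = 0.5, label = label),
    class = "trunc_beta_prior"
  )
}

#' @export
print.trunc_beta_prior <- function(x, ...) {
  cat(sprintf("Beta(%g, %g) truncated to (%g, 1)  [%s]\n",
              x$a, x$b, x$lower, x$label))
  invisible(x)
}

#' Convert a Cohen's d effect size to a success probability
#'
#' Maps d to a log odds ratio via `logodds = d * pi / sqrt(3)` (the
#' standard logistic-variance scaling) and then through the inverse logit,
#' so d = 0 corresponds to the 50% chance level.
#'
#' @param d Cohen's d (finite numeric, vectorized).
#' @return success probability in (0, 1).
#' @examples
#' d_to_probability(0.5)  # 0.712
#' @export
d_to_probability <- function(d) {
  stopifnot(is.numeric(d), all(is.finite(d)))
  stats::plogis(d * pi / sqrt(3))
}

#' Inverse of [d_to_probability()]
#'
#' @param p success probability strictly inside (0, 1).
#' @return Cohen's d.
#' @export
probability_to_d <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)", call. = FALSE)
  stats::qlogis(p) * sqrt(3) / pi
}

#' Prior mass of a truncated beta prior on an interval
#'
#' Probability assigned by the renormalized prior to `[lo, hi]`, with
#' `0.5 <= lo <= hi <= 1`. Computed from the regularized incomplete beta
#' function (upper-tail log form for stability at large shapes).
#'
#' @param prior a [make_prior()] object.
#' @param lo,hi interval bounds within `[0.5, 1]`.
#' @export
truncated_mass <- function(prior, lo, hi) {
  stopifnot(inherits(prior, "trunc_beta_prior"))
  if (any(lo < prior$lower - 1e-12) || any(hi > 1 + 1e-12) || any(lo > hi)) {
    stop("interval must satisfy 0.5 <= lo <= hi <= 1", call. = FALSE)
  }
  tail <- function(q) stats::pbeta(q, prior$a, prior$b, lower.tail = FALSE)
  (tail(lo) - tail(hi)) / tail(prior$lower)
}

#' Quantile of a truncated beta prior
#'
#' Value `x` in (0.5, 1) with `truncated_mass(prior, 0.5, x) == q`.
#'
#' @param prior a [make_prior()] object.
#' @param q cumulative truncated mass in (0, 1), vectorized.
#' @export
truncated_quantile <- function(prior, q) {
  stopifnot(inherits(prior, "trunc_beta_prior"))
  if (any(q <= 0 | q >= 1)) stop("q must lie strictly in (0, 1)", call. = FALSE)
  mass_below <- stats::pbeta(prior$lower, prior$a, prior$b)
  stats::qbeta(mass_below + q * (1 - mass_below), prior$a, prior$b)
}

#' Density of a truncated beta prior
#'
#' Zero below the truncation point; the beta density divided by the upper
#' tail mass above it. For symmetric shapes (a = b) this is exactly twice
#' the untruncated density.
#'
#' @param prior a [make_prior()] object.
#' @param x evaluation points (vectorized).
#' @export
truncated_density <- function(prior, x) {
  stopifnot(inherits(prior, "trunc_beta_prior"))
  out <- numeric(length(x))
  in_support <- x > prior$lower & x <= 1
  norm <- stats::pbeta(prior$lower, prior$a, prior$b, lower.tail = FALSE)
  out[in_support] <- stats::dbeta(x[in_support], prior$a, prior$b) / norm
  out
}
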