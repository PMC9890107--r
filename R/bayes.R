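#' Bayes factor for pooled binomial counts: point null versus a truncated beta prior
#'
#' Contrasts M0 (every guess succeeds with probability exactly 0.5) against
#' M1 (success probability p drawn from a beta prior truncated to (0.5, 1)).
#' BF01 is the marginal likelihood of the pooled counts under M0 divided by
#' the marginal under M1:
#'
#' \deqn{BF_{01} = \frac{0.5^n \, B(a,b) \,(1 - I_{0.5}(a,b))}
#'                      {B(k+a,\, n-k+b)\,(1 - I_{0.5}(k+a,\, n-k+b))}}
#'
#' where I is the regularized incomplete beta function. Everything is
#' evaluated in log space; `lbeta()` and the log upper tail of `pbeta()`
#' keep the ratio stable up to n in the 10^5 range and shapes in the 10^3
#' range. BF01 > 1 favours the chance model.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials.
#' @param prior a [make_prior()] object.
#' @param log return log(BF01) instead (the BF itself under- or overflows
#'   double precision once the evidence is overwhelming, around |log BF|
#'   > 709).
#' @return BF01 as a positive scalar; 1 when n = 0 (no data).
#' @examples
#' bf01(60, 100, make_prior("uniform"))
#' @export
bf01 <- function(k, n, prior, log = FALSE) {
  stopifnot(inherits(prior, "trunc_beta_prior"),
            length(k) == 1, length(n) == 1, n >= 0)
  if (k < 0 || k > n) stop("k must satisfy 0 <= k <= n", call. = FALSE)
  if (n == 0) return(if (log) 0 else 1)
  lbf <- log_bf01(k, n, prior$a, prior$b)
  if (log) lbf else exp(lbf)
}

# log BF01 for vectors of k (shared n and prior shapes); workhorse for
# trajectories and simulation where constructing prior objects per call
# would dominate run time.
log_bf01 <- function(k, n, a, b) {
  log_m0 <- n * log(0.5)
  log_tail <- function(s1, s2) stats::pbeta(0.5, s1, s2, lower.tail = FALSE, log.p = TRUE)
  log_m1 <- lbeta(k + a, n - k + b) - lbeta(a, b) +
    log_tail(k + a, n - k + b) - log_tail(a, b)
  log_m0 - log_m1
}

#' Classify a Bayes factor against the registered evidence thresholds
#'
#' @param bf01 the Bayes factor BF01 (evidence for the chance model).
#' @param upper threshold above which the test supports M0 (default 25).
#' @param lower threshold below which the test supports M1 (default 1/25).
#' @return one of `"support_M0"`, `"support_M1"`, `"inconclusive"`.
#' @export
bf_verdict <- function(bf01, upper = 25, lower = 1 / 25) {
  stopifnot(lower < 1, upper > 1)
  ifelse(bf01 > upper, "support_M0",
         ifelse(bf01 < lower, "support_M1", "inconclusive"))
}

#' Conjugate beta posterior for the robustness parameter estimate
#'
#' Updates an (untruncated) Beta(prior_a, prior_b) prior with k successes in
#' n trials. The default prior Beta(829, 733) encodes the original
#' experiment's 828 successes and 732 failures. Note the deliberate
#' asymmetry with the Bayes-factor tests: the robustness posterior uses the
#' plain beta prior over (0, 1), while the BF priors are truncated to
#' (0.5, 1).
#'
#' @param k,n pooled successes and trials.
#' @param prior_a,prior_b prior beta shapes (defaults 829, 733).
#' @param hdi_level mass of the reported highest density interval.
#' @param rope_hi upper edge of the region of practical equivalence
#'   `[0, rope_hi]` on the success-probability scale.
#' @return list with posterior shapes `post_a`, `post_b`, the posterior
#'   `mode`, the HDI bounds, `mass_in_rope`, `tail_above_rope` and the ROPE
#'   `verdict`.
#' @export
posterior_update <- function(k, n, prior_a = 829, prior_b = 733,
                             hdi_level = 0.90, rope_hi = 0.506) {
  stopifnot(k >= 0, k <= n, prior_a > 0, prior_b > 0)
  post_a <- prior_a + k
  post_b <- prior_b + (n - k)
  interval <- beta_hdi(post_a, post_b, level = hdi_level)
  mass_in <- stats::pbeta(rope_hi, post_a, post_b)
  out <- list(
    post_a = post_a, post_b = post_b,
    mode = (post_a - 1) / (post_a + post_b - 2),
    hdi_level = hdi_level, hdi_lo = interval[[1]], hdi_hi = interval[[2]],
    rope_hi = rope_hi,
    mass_in_rope = mass_in, tail_above_rope = 1 - mass_in
  )
  out$verdict <- rope_decision(out)
  out
}

#' Highest density interval of a beta distribution
#'
#' The shortest interval holding `level` posterior mass. Requires both
#' shapes > 1 (strictly unimodal interior mode); found by minimizing the
#' interval width over the lower endpoint, with the upper endpoint tied to
#' it through the fixed-mass constraint `hi = Q(P(lo) + level)`.
#'
#' @param a,b beta shapes, both > 1.
#' @param level interval mass in (0, 1).
#' @return numeric vector `c(lo, hi)`.
#' @export
beta_hdi <- function(a, b, level = 0.90) {
  stopifnot(level > 0, level < 1)
  if (a <= 1 || b <= 1) {
    stop("HDI requires an interior mode (both shapes > 1)", call. = FALSE)
  }
  width <- function(lo) {
    stats::qbeta(stats::pbeta(lo, a, b) + level, a, b) - lo
  }
  lo_max <- stats::qbeta(1 - level, a, b)
  opt <- stats::optimize(width, interval = c(0, lo_max), tol = 1e-12)
  lo <- opt$minimum
  c(lo, stats::qbeta(stats::pbeta(lo, a, b) + level, a, b))
}

#' Region-of-practical-equivalence decision on a beta posterior
#'
#' More than `mass_threshold` of the posterior inside `[0, rope_hi]`
#' supports the chance model; more than `mass_threshold` outside supports
#' the above-chance model; anything else is inconclusive.
#'
#' @param summary a [posterior_update()] result (or any list with
#'   `post_a`, `post_b`).
#' @param rope_hi upper ROPE edge; defaults to the value stored in
#'   `summary` if present, else 0.506.
#' @param mass_threshold decision threshold (default 0.95).
#' @export
rope_decision <- function(summary, rope_hi = NULL, mass_threshold = 0.95) {
  if (is.null(rope_hi)) rope_hi <- if (!is.null(summary$rope_hi)) summary$rope_hi else 0.506
  mass_in <- stats::pbeta(rope_hi, summary$post_a, summary$post_b)
  if (mass_in > mass_threshold) "support_M0"
  else if (1 - mass_in > mass_threshold) "support_M1"
  else "inconclusive"
}
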