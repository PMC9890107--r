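#' Collapse a trial table to per-participant sufficient statistics
#'
#' For an intercept-only random-effects logistic model the data enter the
#' marginal likelihood only through each participant's (successes, trials)
#' pair, so participants sharing a pair can be collapsed to a pattern with
#' a count. This is what makes design-calibration simulation affordable.
#'
#' @param table a confirmatory-filtered [trial_table()].
#' @return data frame with columns `k`, `n`, `count`, one row per distinct
#'   (successes, trials) pattern.
#' @export
collapse_patterns <- function(table) {
  stopifnot(inherits(table, "trial_table"))
  if (!nrow(table)) return(data.frame(k = integer(0), n = integer(0), count = integer(0)))
  k_i <- tapply(table$success, table$participant_id, sum)
  n_i <- tapply(table$success, table$participant_id, length)
  collapse_counts(as.integer(k_i), as.integer(n_i))
}

# collapse per-participant (k_i, n_i) vectors into pattern counts
collapse_counts <- function(k_i, n_i) {
  key <- paste(k_i, n_i)
  tab <- table(key)
  parts <- strsplit(names(tab), " ", fixed = TRUE)
  data.frame(
    k = vapply(parts, function(p) as.integer(p[[1]]), integer(1)),
    n = vapply(parts, function(p) as.integer(p[[2]]), integer(1)),
    count = as.integer(tab)
  )
}

# numerically stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- x
  small <- x < 35
  out[small] <- log1p(exp(x[small]))
  out
}

# Gauss-Hermite nodes/weights, cached (physicists' convention: weight
# function exp(-x^2))
gh_cache <- new.env(parent = emptyenv())
gh_rule <- function(q = 21L) {
  key <- as.character(q)
  if (is.null(gh_cache[[key]])) gh_cache[[key]] <- pracma::gaussHermite(q)
  gh_cache[[key]]
}

# Marginal log-likelihood of collapsed patterns under the random-intercept
# logistic model, by adaptive Gauss-Hermite quadrature: each pattern's
# integrand is standardized at its conditional mode and curvature before
# applying the rule, which keeps 21 nodes accurate for tau up to ~2.
# Includes the binomial coefficient so values are comparable with glmer's
# logLik on an aggregated binomial response.
agq_loglik <- function(beta0, tau, k, n, count, q = 21L) {
  if (tau < 1e-8) {
    eta <- beta0
    return(sum(count * (lchoose(n, k) + k * eta - n * log1pexp(eta))))
  }
  gh <- gh_rule(q)
  inv_tau2 <- 1 / tau^2
  # Newton for the conditional mode of h(u) = k*eta - n*log(1+e^eta) - u^2/(2tau^2)
  u <- numeric(length(k))
  for (iter in 1:50) {
    p <- stats::plogis(beta0 + u)
    grad <- k - n * p - u * inv_tau2
    curv <- -(n * p * (1 - p) + inv_tau2)
    step <- grad / curv
    u <- u - step
    if (max(abs(step)) < 1e-11) break
  }
  p <- stats::plogis(beta0 + u)
  sigma <- 1 / sqrt(n * p * (1 - p) + inv_tau2)
  # nodes per pattern: u_hat + sqrt(2) * sigma * x_j
  U <- outer(u, rep(1, q)) + outer(sqrt(2) * sigma, gh$x)
  eta <- beta0 + U
  logf <- k * eta - n * log1pexp(eta) +
    stats::dnorm(U, 0, tau, log = TRUE) +
    outer(rep(1, length(k)), gh$x^2 + log(gh$w)) +
    log(sqrt(2) * sigma)
  m <- apply(logf, 1, max)
  log_int <- m + log(rowSums(exp(logf - m)))
  sum(count * (lchoose(n, k) + log_int))
}

#' Fit the intercept-only random-intercept logistic regression
#'
#' Maximizes the marginal likelihood of collapsed (successes, trials)
#' patterns, integrating the participant intercepts u_i ~ N(0, tau^2) out
#' by adaptive Gauss--Hermite quadrature (21 nodes, mode-and-curvature
#' standardization per pattern). The optimizer works on (beta0, log tau);
#' the tau = 0 boundary is handled by comparing against the profiled
#' fixed-effects fit. The standard error of the intercept is the
#' (beta0, beta0) entry of the inverse observed information of the
#' marginal log-likelihood (binomial Wald information at the boundary).
#'
#' @param x a [trial_table()] or a collapsed pattern data frame with
#'   columns `k`, `n`, `count` (see [collapse_patterns()]).
#' @param quad_points number of quadrature nodes.
#' @return list of class `mixed_fit`: `beta0`, `tau`, `se_beta0`,
#'   `loglik`, `n_participants`, `n_trials`, `converged`.
#' @export
fit_random_intercept_logistic <- function(x, quad_points = 21L) {
  pat <- if (inherits(x, "trial_table")) collapse_patterns(x) else x
  stopifnot(all(c("k", "n", "count") %in% names(pat)))
  if (!nrow(pat) || sum(pat$count) < 1) stop("no participants to fit", call. = FALSE)
  k <- pat$k; n <- pat$n; cnt <- pat$count
  ktot <- sum(k * cnt); ntot <- sum(n * cnt)
  n_participants <- sum(cnt)

  fail <- function() structure(list(
    beta0 = NA_real_, tau = NA_real_, se_beta0 = NA_real_, loglik = NA_real_,
    n_participants = n_participants, n_trials = ntot, converged = FALSE
  ), class = "mixed_fit")
  if (ktot == 0 || ktot == ntot) return(fail())  # intercept diverges

  beta_fixed <- stats::qlogis(ktot / ntot)
  ll_fixed <- agq_loglik(beta_fixed, 0, k, n, cnt, quad_points)

  negll <- function(par) -agq_loglik(par[[1]], exp(par[[2]]), k, n, cnt, quad_points)
  opt <- stats::optim(c(beta_fixed, log(0.15)), negll, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 500))
  boundary <- opt$convergence != 0 || -opt$value <= ll_fixed + 1e-7 ||
    exp(opt$par[[2]]) < 1e-4

  if (boundary) {
    p_hat <- ktot / ntot
    info <- ntot * p_hat * (1 - p_hat)  # observed info for the logit intercept
    return(structure(list(
      beta0 = beta_fixed, tau = 0, se_beta0 = 1 / sqrt(info),
      loglik = ll_fixed, n_participants = n_participants, n_trials = ntot,
      converged = TRUE
    ), class = "mixed_fit"))
  }

  hess <- stats::optimHess(opt$par, negll)
  vcov_b <- tryCatch(solve(hess)[1, 1], error = function(e) NA_real_)
  if (!is.finite(vcov_b) || vcov_b <= 0) return(fail())
  structure(list(
    beta0 = opt$par[[1]], tau = exp(opt$par[[2]]), se_beta0 = sqrt(vcov_b),
    loglik = -opt$value, n_participants = n_participants, n_trials = ntot,
    converged = TRUE
  ), class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf(
    "Random-intercept logistic fit: beta0 = %.4f (se %.4f), tau = %.4f, logLik = %.2f\n  %d participants, %d trials%s\n",
    x$beta0, x$se_beta0, x$tau, x$loglik, x$n_participants, x$n_trials,
    if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Wald confidence interval for the success probability
#'
#' Interval `inverse_logit(beta0 +/- z * se)` from a converged mixed-model
#' fit, on the probability scale.
#'
#' @param fit a [fit_random_intercept_logistic()] result.
#' @param level confidence level.
#' @return list with `level`, `lo`, `hi`, `estimate`.
#' @export
probability_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "mixed_fit"))
  if (!isTRUE(fit$converged)) stop("cannot form a CI from an unconverged fit", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(level = level,
       lo = stats::plogis(fit$beta0 - z * fit$se_beta0),
       hi = stats::plogis(fit$beta0 + z * fit$se_beta0),
       estimate = stats::plogis(fit$beta0))
}

#' Equivalence-style verdict from a probability-scale confidence interval
#'
#' The chance model is supported when the whole interval sits below the
#' smallest effect of interest (upper bound < `sesoi`); failing that, the
#' above-chance model is supported when the interval excludes chance
#' (lower bound > `null`); otherwise the test is inconclusive. The M0
#' check deliberately comes first.
#'
#' @param ci a [probability_ci()] result (or list with `lo`, `hi`).
#' @param sesoi smallest effect size of interest on the probability scale.
#' @param null chance success probability.
#' @export
ci_verdict <- function(ci, sesoi = 0.51, null = 0.50) {
  if (ci$hi < sesoi) "support_M0"
  else if (ci$lo > null) "support_M1"
  else "inconclusive"
}

#' Bonferroni-widened confidence level for a given analysis point
#'
#' Two one-sided CI checks are made per look, so the two-sided level at
#' look L is `1 - base_alpha / (2 L)`: 99.75%, 99.875%, 99.91667%,
#' 99.9375%, 99.95% for looks 1--5 at the registered alpha of 0.005.
#'
#' @param look 1-based analysis-point index (vectorized).
#' @param base_alpha overall one-sided test size.
#' @export
ci_level_for_look <- function(look, base_alpha = 0.005) {
  stopifnot(all(look >= 1))
  1 - base_alpha / (2 * look)
}

#' One-sided binomial robustness tests for the pooled counts
#'
#' First tests the null "success chance >= sesoi" (lower-tail rejection
#' supports M0); only if that is not rejected, tests "success chance <=
#' null" (upper-tail rejection supports M1); otherwise inconclusive.
#' Exact binomial tails by default; a normal-approximation variant is
#' available for comparison with z-based analyses.
#'
#' @param k,n pooled successes and trials.
#' @param sesoi,null hypothesized bounds on the probability scale.
#' @param alpha significance threshold (default 0.005).
#' @param method `"exact"` (binomial tails) or `"normal"`.
#' @return list with `verdict`, `p_le_sesoi` (lower tail under sesoi) and
#'   `p_gt_null` (upper tail under the chance null).
#' @export
one_sided_proportion_tests <- function(k, n, sesoi = 0.51, null = 0.50,
                                       alpha = 0.005,
                                       method = c("exact", "normal")) {
  method <- match.arg(method)
  stopifnot(n >= 1, k >= 0, k <= n)
  if (method == "exact") {
    p_le <- stats::pbinom(k, n, sesoi)
    p_gt <- stats::pbinom(k - 1, n, null, lower.tail = FALSE)
  } else {
    z1 <- (k / n - sesoi) / sqrt(sesoi * (1 - sesoi) / n)
    z2 <- (k / n - null) / sqrt(null * (1 - null) / n)
    p_le <- stats::pnorm(z1)
    p_gt <- stats::pnorm(z2, lower.tail = FALSE)
  }
  verdict <- if (p_le < alpha) "support_M0"
  else if (p_gt < alpha) "support_M1"
  else "inconclusive"
  list(verdict = verdict, p_le_sesoi = p_le, p_gt_null = p_gt)
}
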