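test_that("pattern collapsing preserves participant counts and the likelihood", {
  tab <- participants_fixture(c(0.5, 0.5, 10 / 18))
  pat <- collapse_patterns(tab)
  expect_equal(pat[order(pat$k), ],
               data.frame(k = c(9L, 10L), n = 18L, count = c(2L, 1L)),
               ignore_attr = TRUE)
  expect_equal(sum(pat$count), 3)
  expect_equal(sum(pat$n * pat$count), nrow(tab))
  expect_equal(nrow(collapse_patterns(tab[0, ])), 0L)

  # collapsed marginal log-likelihood equals the participant-by-participant sum
  set.seed(21)
  k_i <- stats::rbinom(40, 18, stats::plogis(stats::rnorm(40, 0.2, 0.6)))
  pat <- seqpsi:::collapse_counts(k_i, rep(18L, 40))
  flat <- data.frame(k = k_i, n = 18L, count = 1L)
  for (par in list(c(0.1, 0.4), c(-0.3, 0.9), c(0, 1e-9))) {
    expect_equal(seqpsi:::agq_loglik(par[1], par[2], pat$k, pat$n, pat$count),
                 seqpsi:::agq_loglik(par[1], par[2], flat$k, flat$n, flat$count),
                 tolerance = 1e-10)
  }
})

test_that("perfectly balanced data drive the fit to the boundary beta0 = 0, tau = 0", {
  tab <- participants_fixture(rep(0.5, 6))
  fit <- fit_random_intercept_logistic(tab)
  expect_true(fit$converged)
  expect_equal(fit$beta0, 0, tolerance = 1e-8)
  expect_equal(fit$tau, 0)
  # boundary fit reduces to the single-proportion Wald logit interval
  ci <- probability_ci(fit, 0.95)
  p <- 0.5; n <- 6 * 18
  half <- stats::qnorm(0.975) / sqrt(n * p * (1 - p))
  expect_equal(c(ci$lo, ci$hi), stats::plogis(c(-half, half)), tolerance = 1e-10)
})

test_that("the marginal-likelihood optimum matches an independent-quadrature oracle on toy data", {
  pat <- data.frame(k = c(3L, 14L), n = 18L, count = c(1L, 1L))
  # oracle: marginal likelihood by adaptive interval quadrature, not AGQ
  oracle_ll <- function(beta0, tau) {
    sum(pat$count * log(mapply(function(k, n) {
      stats::integrate(function(u) {
        p <- stats::plogis(beta0 + u)
        choose(n, k) * p^k * (1 - p)^(n - k) * stats::dnorm(u, 0, tau)
      }, -Inf, Inf, rel.tol = 1e-12)$value
    }, pat$k, pat$n)))
  }
  grid <- expand.grid(beta0 = seq(-0.4, 0.4, by = 0.02),
                      tau = seq(0.3, 1.8, by = 0.02))
  ll <- mapply(oracle_ll, grid$beta0, grid$tau)
  start <- grid[which.max(ll), ]
  ref <- stats::optim(c(start$beta0, log(start$tau)),
                      function(par) -oracle_ll(par[1], exp(par[2])),
                      control = list(reltol = 1e-14, maxit = 2000))
  fit <- fit_random_intercept_logistic(pat)
  expect_equal(fit$beta0, ref$par[[1]], tolerance = 1e-4)
  expect_equal(fit$tau, exp(ref$par[[2]]), tolerance = 1e-4)
  expect_equal(fit$loglik, -ref$value, tolerance = 1e-8)
})

test_that("fit agrees with the lme4 reference on heterogeneous data", {
  skip_if_not_installed("lme4")
  set.seed(33)
  k_i <- stats::rbinom(250, 18, stats::plogis(stats::rnorm(250, 0.15, 0.5)))
  pat <- seqpsi:::collapse_counts(k_i, rep(18L, 250))
  fit <- fit_random_intercept_logistic(pat)

  df <- data.frame(k = k_i, id = factor(seq_along(k_i)))
  g <- lme4::glmer(cbind(k, 18 - k) ~ 1 + (1 | id), family = binomial,
                   data = df, nAGQ = 25)
  expect_equal(fit$beta0, unname(lme4::fixef(g)), tolerance = 1e-4)
  expect_equal(fit$tau, sqrt(unlist(lme4::VarCorr(g))[[1]]), tolerance = 1e-3)
  expect_equal(fit$se_beta0, sqrt(as.numeric(lme4::vcov.merMod(g)[1, 1])),
               tolerance = 1e-3)
})

test_that("the reported optimum is stable in the number of quadrature nodes", {
  set.seed(34)
  k_i <- stats::rbinom(120, 18, stats::plogis(stats::rnorm(120, 0, 0.7)))
  pat <- seqpsi:::collapse_counts(k_i, rep(18L, 120))
  fit <- fit_random_intercept_logistic(pat)
  l21 <- seqpsi:::agq_loglik(fit$beta0, fit$tau, pat$k, pat$n, pat$count, 21L)
  l51 <- seqpsi:::agq_loglik(fit$beta0, fit$tau, pat$k, pat$n, pat$count, 51L)
  expect_lt(abs(l21 - l51), 1e-8)
})

test_that("probability-scale CI transforms the Wald interval monotonically", {
  fit <- structure(list(beta0 = 0, se_beta0 = 0.1, converged = TRUE),
                   class = "mixed_fit")
  ci <- probability_ci(fit, 0.95)
  expect_equal(c(ci$lo, ci$hi),
               stats::plogis(c(-1, 1) * stats::qnorm(0.975) * 0.1),
               tolerance = 1e-12)
  expect_equal(round(c(ci$lo, ci$hi), 4), c(0.4512, 0.5488))
  expect_lt(ci$lo, ci$estimate); expect_gt(ci$hi, ci$estimate)

  tiny <- structure(list(beta0 = 0.3, se_beta0 = 1e-12, converged = TRUE),
                    class = "mixed_fit")
  ci0 <- probability_ci(tiny, 0.99)
  expect_equal(ci0$lo, ci0$hi, tolerance = 1e-9)

  bad <- structure(list(converged = FALSE), class = "mixed_fit")
  expect_error(probability_ci(bad), "unconverged")
})

test_that("CI verdicts apply the equivalence bounds in the registered order", {
  expect_equal(ci_verdict(list(lo = 0.4911, hi = 0.5067)), "support_M0")
  expect_equal(ci_verdict(list(lo = 0.502, hi = 0.520)), "support_M1")
  expect_equal(ci_verdict(list(lo = 0.495, hi = 0.515)), "inconclusive")
  # M0 check has precedence even when the interval also excludes chance
  expect_equal(ci_verdict(list(lo = 0.501, hi = 0.505)), "support_M0")
})

test_that("the Bonferroni schedule reproduces the registered confidence levels", {
  expect_equal(ci_level_for_look(1:4),
               c(0.9975, 0.99875, 0.9991667, 0.999375), tolerance = 1e-7)
  expect_equal(ci_level_for_look(5), 0.9995)
})

test_that("one-sided binomial robustness tests match exact tails and order", {
  low <- one_sided_proportion_tests(400, 1000)
  expect_equal(low$verdict, "support_M0")
  expect_equal(low$p_le_sesoi, stats::pbinom(400, 1000, 0.51))

  high <- one_sided_proportion_tests(600, 1000)
  expect_equal(high$verdict, "support_M1")
  expect_equal(high$p_gt_null,
               stats::binom.test(600, 1000, 0.5, alternative = "greater")$p.value)

  mid <- one_sided_proportion_tests(505, 1000)
  expect_equal(mid$verdict, "inconclusive")
  expect_gt(mid$p_le_sesoi, 0.005); expect_gt(mid$p_gt_null, 0.005)

  approx <- one_sided_proportion_tests(600, 1000, method = "normal")
  expect_equal(approx$verdict, "support_M1")
  expect_equal(approx$p_gt_null,
               stats::pnorm((0.6 - 0.5) / sqrt(0.25 / 1000), lower.tail = FALSE))
})
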