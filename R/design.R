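#' Registered sequential design configuration
#'
#' Bundles every preregistered constant of the sequential hybrid design:
#' the cumulative erotic-trial analysis points, the Bayes-factor evidence
#' thresholds, the smallest effect size of interest and chance bound for
#' the confidence-interval test, the base alpha feeding the Bonferroni CI
#' schedule, the ROPE and HDI settings of the robustness test, and the
#' three truncated beta priors. The defaults are the registered values;
#' a bare `design_config()` reproduces the registered design.
#'
#' @param analysis_points strictly increasing cumulative erotic-trial
#'   counts at which the four tests are evaluated.
#' @param bf_upper,bf_lower BF01 thresholds supporting M0 / M1
#'   (must satisfy `bf_lower = 1 / bf_upper`).
#' @param sesoi,null_bound CI-test probability bounds.
#' @param base_alpha one-sided size for the Bonferroni CI schedule.
#' @param rope_hi,hdi_level robustness-test settings.
#' @param priors named list of [make_prior()] objects used by the BF tests.
#' @export
design_config <- function(analysis_points = c(37836L, 62388L, 86958L, 111528L, 136080L),
                          bf_upper = 25, bf_lower = 1 / 25,
                          sesoi = 0.51, null_bound = 0.50,
                          base_alpha = 0.005,
                          rope_hi = 0.506, hdi_level = 0.90,
                          priors = list(uniform = make_prior("uniform"),
                                        buj = make_prior("buj"),
                                        replication = make_prior("replication"))) {
  stopifnot(all(diff(analysis_points) > 0),
            abs(bf_lower - 1 / bf_upper) < 1e-12,
            all(vapply(priors, inherits, logical(1), "trunc_beta_prior")))
  structure(list(analysis_points = as.integer(analysis_points),
                 bf_upper = bf_upper, bf_lower = bf_lower,
                 sesoi = sesoi, null_bound = null_bound,
                 base_alpha = base_alpha,
                 rope_hi = rope_hi, hdi_level = hdi_level,
                 priors = priors),
            class = "design_config")
}

# Four-test decision from sufficient statistics: pooled counts for the
# three Bayes-factor tests, collapsed patterns for the mixed-model CI
# test. Shared by evaluate_look() and the design simulator.
look_decision <- function(k, n, patterns, look, cfg) {
  lbf <- vapply(cfg$priors, function(pr) log_bf01(k, n, pr$a, pr$b), numeric(1))
  bf <- exp(lbf)
  bf_v <- bf_verdict(bf, cfg$bf_upper, cfg$bf_lower)

  fit <- fit_random_intercept_logistic(patterns)
  level <- ci_level_for_look(look, cfg$base_alpha)
  if (isTRUE(fit$converged)) {
    ci <- probability_ci(fit, level)
    civ <- ci_verdict(ci, cfg$sesoi, cfg$null_bound)
  } else {
    ci <- list(level = level, lo = NA_real_, hi = NA_real_, estimate = NA_real_)
    civ <- "inconclusive"
  }

  verdicts <- c(ci = civ, bf_v)
  conjunction <- if (all(verdicts == "support_M0")) "stop_support_M0"
  else if (all(verdicts == "support_M1")) "stop_support_M1"
  else "continue"

  list(look = look, n_trials = n, k = k,
       fit = fit, ci = ci, ci_verdict = civ,
       bf01 = bf, bf_verdicts = bf_v,
       conjunction = conjunction)
}

#' Evaluate the four simultaneous tests at one analysis point
#'
#' Runs the mixed-model CI test (at the look's Bonferroni-widened level)
#' and the three Bayes-factor tests on the pooled counts of a trial table
#' already truncated to the look's analysis point, and combines them by
#' the conjunction rule: the study stops only when all four verdicts agree
#' on the same model.
#'
#' @param table confirmatory-filtered [trial_table()] truncated to
#'   `cfg$analysis_points[look]` erotic trials.
#' @param look 1-based analysis-point index.
#' @param cfg a [design_config()].
#' @return list of class `look_result` with the pooled counts, fit, CI,
#'   per-prior BF01 values, the five verdicts and the `conjunction`
#'   (`"stop_support_M0"`, `"stop_support_M1"` or `"continue"`).
#' @export
evaluate_look <- function(table, look, cfg = design_config()) {
  stopifnot(inherits(table, "trial_table"),
            look >= 1, look <= length(cfg$analysis_points))
  expected <- cfg$analysis_points[[look]]
  if (nrow(table) < expected) {
    stop("insufficient trials for look ", look, ": need ", expected,
         ", have ", nrow(table), call. = FALSE)
  }
  counts <- pooled_success_counts(table)
  res <- look_decision(counts[["k"]], counts[["n"]], collapse_patterns(table),
                       look, cfg)
  class(res) <- "look_result"
  res
}

#' @export
print.look_result <- function(x, ...) {
  cat(sprintf("Look %d: k = %d / n = %d (%.2f%%)\n", x$look, x$k, x$n_trials,
              100 * x$k / x$n_trials))
  cat(sprintf("  CI (%.5f): [%.4f, %.4f] -> %s\n", x$ci$level, x$ci$lo, x$ci$hi,
              x$ci_verdict))
  for (nm in names(x$bf01)) {
    cat(sprintf("  BF01 (%s): %.4g -> %s\n", nm, x$bf01[[nm]], x$bf_verdicts[[nm]]))
  }
  cat("  conjunction:", x$conjunction, "\n")
  invisible(x)
}

#' Run the full sequential study over a deposited trial stream
#'
#' Applies the confirmatory filter, then walks the pre-specified analysis
#' points in order, evaluating the four-test conjunction at each and
#' stopping at the first decisive look. If the stream is exhausted before
#' the next analysis point and no decision has been reached, the analysis
#' point has not been reached and an error is raised. Reaching the final
#' look without a decision yields an inconclusive study.
#'
#' @param stream raw [trial_table()] in deposit order.
#' @param cfg a [design_config()].
#' @param test_experimenter_ids passed to [filter_confirmatory()].
#' @return list of class `study_outcome`: `looks` (evaluated look
#'   results), `final` (`"support_M0"`, `"support_M1"` or
#'   `"inconclusive"`), `stopped_at_look`, `trials_used`.
#' @export
run_study <- function(stream, cfg = design_config(),
                      test_experimenter_ids = character(0)) {
  confirmatory <- filter_confirmatory(stream, test_experimenter_ids)
  looks <- list()
  for (look in seq_along(cfg$analysis_points)) {
    point <- cfg$analysis_points[[look]]
    if (nrow(confirmatory) < point) {
      stop("analysis point not reached: look ", look, " needs ", point,
           " erotic trials, stream has ", nrow(confirmatory), call. = FALSE)
    }
    res <- evaluate_look(filter_confirmatory(confirmatory, analysis_point = point),
                         look, cfg)
    looks[[look]] <- res
    if (res$conjunction != "continue") {
      return(structure(list(
        looks = looks,
        final = sub("stop_", "", res$conjunction),
        stopped_at_look = look, trials_used = point
      ), class = "study_outcome"))
    }
  }
  structure(list(looks = looks, final = "inconclusive",
                 stopped_at_look = NA_integer_,
                 trials_used = cfg$analysis_points[[length(cfg$analysis_points)]]),
            class = "study_outcome")
}

#' @export
print.study_outcome <- function(x, ...) {
  cat(sprintf("Sequential study outcome: %s (%s, %d trials used)\n", x$final,
              if (is.na(x$stopped_at_look)) "no early stop"
              else paste0("stopped at look ", x$stopped_at_look),
              x$trials_used))
  invisible(x)
}

#' Cumulative Bayes-factor trajectory over the trial stream
#'
#' Recomputes the three BF01 values on the cumulative pooled counts every
#' `step` erotic trials — the quantity a real-time born-open report would
#' redraw as data arrive. Only the closed-form Bayes factors are tracked
#' between looks; the mixed model is evaluated at analysis points only.
#'
#' @param table confirmatory-filtered [trial_table()].
#' @param cfg a [design_config()] (supplies the priors).
#' @param step recompute interval in trials.
#' @return data frame with `n` (prefix length), `k` (prefix successes) and
#'   one `bf01_<label>` column per prior.
#' @export
bf_trajectory <- function(table, cfg = design_config(), step = 1L) {
  stopifnot(inherits(table, "trial_table"), step >= 1)
  n_tot <- nrow(table)
  if (!n_tot) return(data.frame(n = integer(0), k = integer(0)))
  at <- unique(c(seq(step, n_tot, by = step), n_tot))
  k_cum <- cumsum(table$success)[at]
  out <- data.frame(n = at, k = k_cum)
  for (nm in names(cfg$priors)) {
    pr <- cfg$priors[[nm]]
    out[[paste0("bf01_", nm)]] <-
      exp(mapply(function(k, n) log_bf01(k, n, pr$a, pr$b), k_cum, at))
  }
  out
}
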