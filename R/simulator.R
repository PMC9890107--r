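#' Generative truth models for design calibration
#'
#' Describes the assumed state of the world a simulated study samples
#' from:
#'
#' * `"fixed"`: every guess succeeds with the same probability `p`.
#' * `"beta_sampled"`: one population success chance per simulated
#'   experiment, drawn from Beta(`a`, `b`) (defaults 829, 733, the
#'   posterior of the original experiment) and shared by all participants.
#' * `"heterogeneous"`: per-participant chance `clip(p + N(0, sd), 0, 1)`;
#'   with the default sd of 0.15 about 10% of participants exceed a 70%
#'   chance.
#' * `"sheep_goat"`: symmetric contamination — a fraction `mix[1]` of
#'   participants at `p + mix[2]` ("sheep"), an equal fraction at
#'   `p - mix[2]` ("goats"), the remainder at `p`, keeping the population
#'   mean at `p`.
#'
#' @param kind one of the four model kinds.
#' @param p fixed / mean success chance.
#' @param a,b beta shapes for `"beta_sampled"`.
#' @param sd per-person standard deviation for `"heterogeneous"`.
#' @param mix `c(fraction, delta)` for `"sheep_goat"`.
#' @export
truth_model <- function(kind = c("fixed", "beta_sampled", "heterogeneous", "sheep_goat"),
                        p = 0.5, a = 829, b = 733, sd = 0.15,
                        mix = c(0.1, 0.2)) {
  kind <- match.arg(kind)
  stopifnot(p >= 0, p <= 1, a > 0, b > 0, sd >= 0,
            length(mix) == 2, mix[[1]] >= 0, 2 * mix[[1]] <= 1)
  structure(list(kind = kind, p = p, a = a, b = b, sd = sd, mix = mix),
            class = "truth_model")
}

#' Draw per-participant success chances under a truth model
#'
#' For `"beta_sampled"` a single draw is shared by all participants (the
#' population chance varies between simulated experiments, not within).
#' Chances are clipped to `[0, 1]`.
#'
#' @param truth a [truth_model()].
#' @param n_participants number of chances to draw.
#' @return numeric vector of length `n_participants`.
#' @export
draw_participant_chances <- function(truth, n_participants) {
  stopifnot(inherits(truth, "truth_model"), n_participants >= 0)
  n <- n_participants
  chances <- switch(truth$kind,
    fixed = rep(truth$p, n),
    beta_sampled = rep(stats::rbeta(1, truth$a, truth$b), n),
    heterogeneous = truth$p + stats::rnorm(n, 0, truth$sd),
    sheep_goat = {
      u <- stats::runif(n)
      f <- truth$mix[[1]]; delta <- truth$mix[[2]]
      truth$p + delta * (u < f) - delta * (u >= f & u < 2 * f)
    }
  )
  pmin(1, pmax(0, chances))
}

#' Simulate one complete sequential study
#'
#' Grows a cohort of participants, each contributing
#' `trials_per_participant` erotic trials, until an analysis point is
#' reached; evaluates the full four-test conjunction there; stops at the
#' first decisive look or runs to the final analysis point. Participant
#' success counts are drawn directly as binomials and fed to the
#' mixed model as collapsed patterns — equivalent to materializing every
#' trial row, at a small fraction of the cost. When an analysis point is
#' not a multiple of the per-participant trial count, the participant
#' straddling the cut contributes a partial count at that look and the
#' remainder later.
#'
#' @param truth a [truth_model()].
#' @param cfg a [design_config()].
#' @param trials_per_participant erotic trials per participant (default 18).
#' @param keep_looks keep the full per-look results (default `TRUE`; the
#'   operating-characteristics driver turns it off to save memory).
#' @return a `study_outcome` (see [run_study()]).
#' @export
simulate_study <- function(truth, cfg = design_config(),
                           trials_per_participant = 18L,
                           keep_looks = TRUE) {
  tpp <- as.integer(trials_per_participant)
  stopifnot(tpp >= 1)
  max_n <- cfg$analysis_points[[length(cfg$analysis_points)]]
  max_participants <- ceiling(max_n / tpp)

  chances <- numeric(0)          # drawn lazily as the cohort grows
  k_i <- integer(0)              # per-participant successes so far
  n_i <- integer(0)              # per-participant trials so far
  shared_p <- if (truth$kind == "beta_sampled") draw_participant_chances(truth, 1) else NULL

  looks <- list()
  for (look in seq_along(cfg$analysis_points)) {
    point <- cfg$analysis_points[[look]]
    n_full <- point %/% tpp
    rem <- point - n_full * tpp
    n_needed <- n_full + (rem > 0)
    if (n_needed > length(chances)) {
      new_n <- n_needed - length(chances)
      new_chances <- if (is.null(shared_p)) draw_participant_chances(truth, new_n)
        else rep(shared_p, new_n)
      chances <- c(chances, new_chances)
      k_i <- c(k_i, integer(new_n))
      n_i <- c(n_i, integer(new_n))
    }
    # top participants up to their trial allocation at this look
    target <- c(rep(tpp, n_full), if (rem > 0) rem)
    target <- c(target, integer(length(n_i) - length(target)))
    inc <- target - n_i
    grow <- which(inc > 0)
    if (length(grow)) {
      k_i[grow] <- k_i[grow] + stats::rbinom(length(grow), inc[grow], chances[grow])
      n_i[grow] <- target[grow]
    }
    active <- n_i > 0
    pat <- collapse_counts(k_i[active], n_i[active])
    res <- look_decision(sum(k_i), point, pat, look, cfg)
    if (keep_looks) looks[[look]] <- res
    if (res$conjunction != "continue") {
      return(structure(list(
        looks = looks, final = sub("stop_", "", res$conjunction),
        stopped_at_look = look, trials_used = point
      ), class = "study_outcome"))
    }
  }
  structure(list(looks = looks, final = "inconclusive",
                 stopped_at_look = NA_integer_, trials_used = max_n),
            class = "study_outcome")
}

# derived per-replicate seed, kept below 2^31
replicate_seed <- function(seed, scenario, rep) {
  as.integer((as.numeric(seed) * 48271 + scenario * 99991 + rep * 7919) %%
               2147483629)
}

#' Operating characteristics of the sequential design
#'
#' Monte-Carlo calibration of the whole design: for each truth scenario,
#' simulates `reps` complete sequential studies and tabulates the
#' probability of ending in support of M0, of M1, or inconclusive, the
#' mean number of trials at stopping, the stopping-look distribution and
#' binomial Monte-Carlo standard errors. Replicates use derived
#' sub-seeds, so any scenario row is reproducible in isolation.
#'
#' @param scenarios list of [truth_model()] objects (a single model is
#'   accepted and wrapped).
#' @param reps replicates per scenario.
#' @param cfg a [design_config()].
#' @param seed base integer seed.
#' @param trials_per_participant erotic trials per participant.
#' @return data frame, one row per scenario: `kind`, `p`, `reps`,
#'   `p_support_M0`, `p_support_M1`, `p_inconclusive`, their `se_*`
#'   columns, `mean_trials`, and `stop_look_1` ... `stop_look_L`,
#'   `no_stop` columns.
#' @export
operating_characteristics <- function(scenarios, reps, cfg = design_config(),
                                      seed = 1L, trials_per_participant = 18L) {
  if (inherits(scenarios, "truth_model")) scenarios <- list(scenarios)
  stopifnot(length(scenarios) >= 1, reps >= 1)
  n_looks <- length(cfg$analysis_points)
  rows <- lapply(seq_along(scenarios), function(s) {
    truth <- scenarios[[s]]
    finals <- character(reps)
    stop_look <- integer(reps)
    trials <- numeric(reps)
    for (r in seq_len(reps)) {
      set.seed(replicate_seed(seed, s, r))
      out <- simulate_study(truth, cfg, trials_per_participant, keep_looks = FALSE)
      finals[r] <- out$final
      stop_look[r] <- if (is.na(out$stopped_at_look)) 0L else out$stopped_at_look
      trials[r] <- out$trials_used
    }
    p_hat <- c(M0 = mean(finals == "support_M0"),
               M1 = mean(finals == "support_M1"),
               inc = mean(finals == "inconclusive"))
    se <- sqrt(p_hat * (1 - p_hat) / reps)
    row <- data.frame(kind = truth$kind, p = truth$p, reps = reps,
                      p_support_M0 = p_hat[["M0"]], p_support_M1 = p_hat[["M1"]],
                      p_inconclusive = p_hat[["inc"]],
                      se_M0 = se[["M0"]], se_M1 = se[["M1"]], se_inc = se[["inc"]],
                      mean_trials = mean(trials))
    for (l in seq_len(n_looks)) row[[paste0("stop_look_", l)]] <- mean(stop_look == l)
    row$no_stop <- mean(stop_look == 0L)
    row
  })
  do.call(rbind, rows)
}
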