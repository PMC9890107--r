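#' Configuration for the synthetic born-open trial stream
#'
#' Describes the study structure the generator emulates: sessions of 36
#' trials, half erotic; a multi-lab roster of experimenters; pre-trial
#' dropout (participants who never produce analyzable data); rare
#' mid-session termination; a small left/right guessing bias; and
#' deposition of rows in fixed-size batches with opaque timestamp tokens.
#' The default rates mirror an actual large multi-lab run: 4.17% pre-trial
#' dropout, 1.18% mid-session termination, a 49.08% left-guess rate.
#'
#' @param n_participants participants recruited (before dropout).
#' @param n_labs,experimenters_per_lab roster structure.
#' @param trials_per_session,erotic_per_session session layout.
#' @param truth a [truth_model()] for erotic-trial success chances.
#' @param left_choice_rate probability a guess is "left".
#' @param pre_trial_dropout_rate fraction contributing no trials at all.
#' @param mid_session_termination_rate fraction of started sessions cut
#'   short at a uniformly random trial.
#' @param batch_size rows per born-open deposit.
#' @export
study_gen_config <- function(n_participants = 100L,
                             n_labs = 3L, experimenters_per_lab = 2L,
                             trials_per_session = 36L, erotic_per_session = 18L,
                             truth = truth_model("fixed", p = 0.5),
                             left_choice_rate = 0.4908,
                             pre_trial_dropout_rate = 0.0417,
                             mid_session_termination_rate = 0.0118,
                             batch_size = 200L) {
  stopifnot(erotic_per_session <= trials_per_session,
            n_participants >= 1, n_labs >= 1, experimenters_per_lab >= 1,
            left_choice_rate >= 0, left_choice_rate <= 1,
            pre_trial_dropout_rate >= 0, pre_trial_dropout_rate <= 1,
            mid_session_termination_rate >= 0, mid_session_termination_rate <= 1,
            inherits(truth, "truth_model"))
  structure(as.list(environment()), class = "study_gen_config")
}

# opaque hex tokens standing in for hashed timestamps
random_tokens <- function(n) {
  sprintf("%08x%08x", sample.int(.Machine$integer.max, n, replace = TRUE),
          sample.int(.Machine$integer.max, n, replace = TRUE))
}

#' Generate one session's trial rows
#'
#' A session is 36 trials; the 18 erotic positions are a
#' without-replacement draw (the protocol draws reward images from a
#' pooled set). The participant's guess is Bernoulli(left rate); on
#' erotic trials success is Bernoulli(p_i) and the target side is then
#' set consistent with the guess and the success flag — equivalent to
#' drawing the target after the guess, for any p_i, and it makes the
#' truth model explicit. Non-erotic successes are drawn at 50% (the
#' hypotheses exclude those trials). At p_i = 0.5 the target marginal is
#' 50% left.
#'
#' @param p_i the participant's erotic-trial success chance.
#' @param cfg a [study_gen_config()].
#' @param ids named list with `session_id`, `participant_id`, `lab_id`,
#'   `experimenter_id`.
#' @param n_trials number of trials actually completed (terminated
#'   sessions stop early); default the full session.
#' @return data frame of trial rows in within-session order (without
#'   `deposit_order`, which [generate_study()] assigns globally).
#' @export
generate_session <- function(p_i, cfg = study_gen_config(),
                             ids = list(session_id = "s1", participant_id = "p1",
                                        lab_id = "lab1", experimenter_id = "e1"),
                             n_trials = cfg$trials_per_session) {
  stopifnot(p_i >= 0, p_i <= 1, n_trials >= 1,
            n_trials <= cfg$trials_per_session)
  erotic_pos <- sample.int(cfg$trials_per_session, cfg$erotic_per_session)
  type <- rep("nonerotic", cfg$trials_per_session)
  type[erotic_pos] <- "erotic"
  type <- type[seq_len(n_trials)]
  guess <- ifelse(stats::runif(n_trials) < cfg$left_choice_rate, "left", "right")
  p_succ <- ifelse(type == "erotic", p_i, 0.5)
  success <- stats::runif(n_trials) < p_succ
  target <- ifelse(success, guess, ifelse(guess == "left", "right", "left"))
  data.frame(
    session_id = ids$session_id, participant_id = ids$participant_id,
    lab_id = ids$lab_id, experimenter_id = ids$experimenter_id,
    trial_index = seq_len(n_trials), trial_type = type,
    guessed_side = guess, target_side = target, success = success,
    timestamp_hash = random_tokens(1),
    stringsAsFactors = FALSE
  )
}

#' Generate a complete synthetic study stream
#'
#' Assigns participants to labs and experimenters round-robin, draws
#' per-participant success chances from the truth model, applies
#' pre-trial dropout (those participants contribute no rows) and
#' mid-session termination (the session ends at a uniform random trial
#' before the last), stitches the surviving sessions into one stream in
#' session order, and assigns the global `deposit_order`. Attitude and
#' belief covariates are drawn uniformly from their scales
#' (experimenter / site-PI paranormal-belief scores 0--36 at the roster
#' level, participant belief and sensation-seeking 1--5).
#'
#' @param cfg a [study_gen_config()].
#' @return a [trial_table()].
#' @export
generate_study <- function(cfg = study_gen_config()) {
  stopifnot(inherits(cfg, "study_gen_config"))
  n <- cfg$n_participants
  lab <- sprintf("lab%02d", ((seq_len(n) - 1L) %% cfg$n_labs) + 1L)
  exp_slot <- ((seq_len(n) - 1L) %/% cfg$n_labs) %% cfg$experimenters_per_lab + 1L
  experimenter <- sprintf("%s_e%02d", lab, exp_slot)

  roster <- unique(experimenter)
  exp_asgs <- stats::setNames(sample(0:36, length(roster), replace = TRUE), roster)
  labs <- unique(lab)
  sitepi_asgs <- stats::setNames(sample(0:36, length(labs), replace = TRUE), labs)

  chances <- draw_participant_chances(cfg$truth, n)
  dropped <- stats::runif(n) < cfg$pre_trial_dropout_rate
  terminated <- stats::runif(n) < cfg$mid_session_termination_rate
  cut_at <- ifelse(terminated,
                   1L + floor(stats::runif(n) * (cfg$trials_per_session - 1L)),
                   cfg$trials_per_session)

  sessions <- vector("list", n)
  for (i in seq_len(n)) {
    if (dropped[i]) next
    rows <- generate_session(
      chances[i], cfg,
      ids = list(session_id = sprintf("sess%05d", i),
                 participant_id = sprintf("part%05d", i),
                 lab_id = lab[i], experimenter_id = experimenter[i]),
      n_trials = cut_at[i]
    )
    rows$experimenter_asgs <- exp_asgs[[experimenter[i]]]
    rows$sitepi_asgs <- sitepi_asgs[[lab[i]]]
    rows$esp_belief <- sample(1:5, 1)
    rows$sensation_seeking <- sample(1:5, 1)
    sessions[[i]] <- rows
  }
  sessions <- sessions[!vapply(sessions, is.null, logical(1))]
  if (!length(sessions)) {
    empty <- generate_session(0.5, cfg)[0, ]
    empty$deposit_order <- numeric(0)
    return(trial_table(empty, source = "generate_study"))
  }
  df <- do.call(rbind, sessions)
  df$deposit_order <- seq_len(nrow(df)) - 1L
  trial_table(df, source = "generate_study")
}
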