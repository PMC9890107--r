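test_that("design configuration validates its registered invariants", {
  cfg <- design_config()
  expect_equal(cfg$analysis_points, c(37836L, 62388L, 86958L, 111528L, 136080L))
  expect_equal(cfg$bf_lower, 1 / cfg$bf_upper)
  expect_named(cfg$priors, c("uniform", "buj", "replication"))
  expect_error(design_config(analysis_points = c(100, 50)))
  expect_error(design_config(bf_upper = 25, bf_lower = 1 / 10))
})

test_that("the conjunction stops only when all four verdicts agree", {
  cfg <- small_design()
  n <- 360L
  # overwhelming below-chance data: every test lands on M0
  pat_m0 <- data.frame(k = 5L, n = 18L, count = 20L)
  dec <- seqpsi:::look_decision(5L * 20L, n, pat_m0, 1L, cfg)
  expect_equal(unname(dec$bf_verdicts), rep("support_M0", 3))
  expect_equal(dec$ci_verdict, "support_M0")
  expect_equal(dec$conjunction, "stop_support_M0")

  # overwhelming above-chance data: every test lands on M1
  pat_m1 <- data.frame(k = 14L, n = 18L, count = 20L)
  dec1 <- seqpsi:::look_decision(14L * 20L, n, pat_m1, 1L, cfg)
  expect_equal(dec1$conjunction, "stop_support_M1")

  # balanced data at a tiny analysis point: BFs inconclusive, no stop
  pat_mid <- data.frame(k = 9L, n = 18L, count = 20L)
  dec2 <- seqpsi:::look_decision(9L * 20L, n, pat_mid, 1L, cfg)
  expect_equal(dec2$conjunction, "continue")
  expect_true("inconclusive" %in% c(dec2$ci_verdict, dec2$bf_verdicts))
})

test_that("evaluate_look demands the analysis-point trial count", {
  cfg <- small_design()
  tab <- participants_fixture(rep(0.5, 10))  # 180 erotic trials
  expect_error(evaluate_look(tab, 1L, cfg), "insufficient trials")
})

test_that("run_study stops early on decisive streams and errors on short ones", {
  cfg <- small_design(points = c(180L, 360L))
  set.seed(41)
  decisive <- generate_study(study_gen_config(
    n_participants = 25L, truth = truth_model("fixed", p = 0.15),
    pre_trial_dropout_rate = 0, mid_session_termination_rate = 0))
  out <- run_study(decisive, cfg)
  expect_s3_class(out, "study_outcome")
  expect_equal(out$final, "support_M0")
  expect_equal(out$stopped_at_look, 1L)
  expect_length(out$looks, 1L)          # a stopped study never looks again
  expect_equal(out$trials_used, 180L)

  short <- participants_fixture(rep(0.5, 5))
  expect_error(run_study(short, cfg), "analysis point not reached")
})

test_that("an exhausted design without agreement is inconclusive", {
  cfg <- small_design(points = c(180L, 360L))
  set.seed(42)
  null_stream <- generate_study(study_gen_config(
    n_participants = 20L, truth = truth_model("fixed", p = 0.5),
    pre_trial_dropout_rate = 0, mid_session_termination_rate = 0))
  out <- run_study(null_stream, cfg)
  # at these tiny analysis points the BF thresholds are unreachable
  expect_equal(out$final, "inconclusive")
  expect_true(is.na(out$stopped_at_look))
  expect_length(out$looks, 2L)
})

test_that("look decisions are invariant to permuting trials within the look prefix", {
  cfg <- small_design(points = c(180L, 360L))
  set.seed(43)
  stream <- generate_study(study_gen_config(
    n_participants = 10L, truth = truth_model("fixed", p = 0.3),
    pre_trial_dropout_rate = 0, mid_session_termination_rate = 0))
  conf <- filter_confirmatory(stream, analysis_point = 180L)
  base <- evaluate_look(conf, 1L, cfg)

  # same trial multiset, rechronologized: the shuffled row order becomes
  # the deposit order
  shuffled <- as.data.frame(conf)[sample(nrow(conf)), ]
  shuffled$deposit_order <- seq_len(nrow(shuffled)) - 1L
  reord <- trial_table(shuffled)
  redo <- evaluate_look(reord, 1L, cfg)
  expect_equal(redo$k, base$k)
  expect_equal(redo$bf01, base$bf01)
  expect_equal(redo$ci$lo, base$ci$lo, tolerance = 1e-8)
  expect_equal(redo$conjunction, base$conjunction)
})

test_that("the BF trajectory is the prefix-count closed form", {
  cfg <- design_config()
  tab <- participants_fixture(c(0.5, 10 / 18, 8 / 18))
  traj <- bf_trajectory(tab, cfg, step = 5L)
  expect_equal(traj$n[nrow(traj)], nrow(tab))
  counts <- pooled_success_counts(tab)
  expect_equal(traj$bf01_buj[nrow(traj)],
               bf01(counts[["k"]], counts[["n"]], cfg$priors$buj))
  # an all-failure prefix accumulates evidence for the chance model
  fails <- participants_fixture(c(0, 0))
  tf <- bf_trajectory(fails, cfg, step = 1L)
  expect_true(all(diff(tf$bf01_uniform) > 0))
  expect_equal(tf$bf01_uniform,
               vapply(seq_len(36), function(n) bf01(0, n, cfg$priors$uniform),
                      numeric(1)))
})

test_that("the registered rules reach the all-M0 conjunction on headline-scale statistics", {
  cfg <- design_config()
  n <- 37836L
  k <- round(0.4989 * n)          # pooled success rate of 49.89%
  expect_equal(ci_verdict(list(lo = 0.4911, hi = 0.5067),
                          cfg$sesoi, cfg$null_bound), "support_M0")
  bf <- vapply(cfg$priors, function(pr) bf01(k, n, pr), numeric(1))
  expect_true(all(bf > cfg$bf_upper))
  expect_equal(unname(bf_verdict(bf, cfg$bf_upper, cfg$bf_lower)),
               rep("support_M0", 3))
  # evidence magnitude under the knowledge-based prior is in the tens
  expect_equal(unname(bf[["buj"]]), 72.9, tolerance = 0.01)
})
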