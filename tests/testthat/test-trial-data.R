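test_that("reading a canonical CSV round-trips the schema, with and without a column map", {
  tab <- make_fixture_table(list(
    list(participant = "p1", session = "s1", experimenter = "e1",
         erotic = c(TRUE, FALSE, TRUE), nonerotic = 3L)
  ))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)

  got <- read_trials(path)
  expect_equal(nrow(got), 6L)
  expect_equal(attr(got, "excluded"), 0L)
  expect_equal(got$success, tab$success)
  expect_equal(got$trial_type, tab$trial_type)

  # same file with renamed headers, recovered through column_map
  renamed <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(renamed)[names(renamed) == "target_side"] <- "targetSide"
  names(renamed)[names(renamed) == "trial_type"] <- "reward_category"
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(renamed, path2, row.names = FALSE)
  got2 <- read_trials(path2, column_map = c(target_side = "targetSide",
                                            trial_type = "reward_category"))
  expect_equal(as.data.frame(got2), as.data.frame(got), ignore_attr = TRUE)

  expect_error(read_trials(path2), "trial_type")
})

test_that("rows failing validation are excluded and counted, never repaired", {
  tab <- make_fixture_table(list(
    list(participant = "p1", session = "s1", experimenter = "e1",
         erotic = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  ))
  df <- as.data.frame(tab)
  df$target_side[3] <- "up"
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)

  got <- read_trials(path)
  expect_equal(nrow(got), 5L)
  expect_equal(attr(got, "excluded"), 1L)
  expect_equal(attr(got, "excluded_rows"), 3L)
})

test_that("born-open batching splits by deposit order and concatenation is lossless", {
  big <- participants_fixture(rep(0.5, 25))  # 450 rows
  sink <- withr::local_tempdir()
  paths <- write_born_open_batches(big, batch_size = 200L, sink = sink)
  expect_length(paths, 3L)
  sizes <- vapply(paths, function(p) nrow(utils::read.csv(p)), numeric(1))
  expect_equal(unname(sizes), c(200, 200, 50))

  sink2 <- withr::local_tempdir()
  expect_length(write_born_open_batches(participants_fixture(rep(0.5, 10)),
                                        batch_size = 180L, sink = sink2), 1L)

  # round trip: concatenate batches, reread, compare canonical fields
  concat <- do.call(rbind, lapply(paths, utils::read.csv,
                                  stringsAsFactors = FALSE,
                                  colClasses = "character"))
  path_all <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(concat, path_all, row.names = FALSE)
  reread <- read_trials(path_all)
  expect_equal(reread$success, big$success)
  expect_equal(reread$deposit_order, big$deposit_order)
  expect_equal(reread$session_id, big$session_id)
})

test_that("confirmatory filter keeps completed erotic trials, drops test accounts, truncates at the analysis point", {
  fx <- three_session_fixture()
  kept <- filter_confirmatory(fx, test_experimenter_ids = "tester")
  expect_equal(nrow(kept), 25L)  # 18 complete + 7 from the terminated session
  expect_true(all(kept$trial_type == "erotic"))
  expect_false("pC" %in% kept$participant_id)

  # idempotence
  expect_equal(as.data.frame(filter_confirmatory(kept, "tester")),
               as.data.frame(kept))

  at20 <- filter_confirmatory(fx, "tester", analysis_point = 20L)
  expect_equal(nrow(at20), 20L)
  expect_equal(sum(at20$participant_id == "pB"), 2L)  # cut mid-session

  # prefix property: the set at a is a prefix of the set at b for a <= b
  at15 <- filter_confirmatory(fx, "tester", analysis_point = 15L)
  expect_equal(as.data.frame(at15), utils::head(as.data.frame(at20), 15))

  expect_error(filter_confirmatory(fx, "tester", analysis_point = 26L),
               "analysis point not reached")

  empty <- filter_confirmatory(fx[0, ], "tester")
  expect_equal(nrow(empty), 0L)
})

test_that("inclusion configuration round-trips through YAML", {
  skip_if_not_installed("yaml")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("column_map:", "  target_side: targetSide",
               "test_experimenter_ids: [tester, demo]",
               "analysis_point: 37836"), path)
  cfg <- read_inclusion_config(path)
  expect_equal(cfg$column_map, c(target_side = "targetSide"))
  expect_equal(cfg$test_experimenter_ids, c("tester", "demo"))
  expect_equal(cfg$analysis_point, 37836L)

  minimal <- withr::local_tempfile(fileext = ".yaml")
  writeLines("test_experimenter_ids: []", minimal)
  cfg2 <- read_inclusion_config(minimal)
  expect_null(cfg2$column_map)
  expect_null(cfg2$analysis_point)
})

test_that("pooled counts and per-participant rates match hand counts", {
  fx <- filter_confirmatory(three_session_fixture(), "tester")
  counts <- pooled_success_counts(fx)
  expect_equal(unname(counts), c(9 + 4, 25))  # hand count on the fixture
  expect_equal(unname(pooled_success_counts(fx[0, ])), c(0, 0))
  expect_equal(fx$success, fx$guessed_side == fx$target_side)

  rates <- participant_success_rates(fx, required_trials = 18L)
  expect_equal(rates, c(pA = 0.5))  # pB has only 7 trials, excluded

  four <- filter_confirmatory(
    participants_fixture(c(0.5, 9 / 18, 10 / 18, 1)), character(0))
  expect_equal(participant_success_rates(four, 18L),
               c(p01 = 0.5, p02 = 0.5, p03 = 10 / 18, p04 = 1))
})
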