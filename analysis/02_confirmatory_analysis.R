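#!/usr/bin/env Rscript

# Step 2 — confirmatory sequential analysis of the deposited stream.
#
# Reassembles the born-open batches written by 01_simulate_stream.R,
# applies the preregistered inclusion rules (erotic trials only,
# truncation at the analysis point), runs the four-test conjunction at
# the first registered look, and tracks the per-trial Bayes-factor
# trajectory a real-time report would display. Outputs:
#   results/look1_report.json   — counts, CI, BF01s, verdicts, conjunction
#   results/bf_trajectory.csv   — BF01 per prior every 200 erotic trials

suppressPackageStartupMessages(library(seqpsi))

sink_dir <- file.path("scratch", "stream")
batches <- list.files(sink_dir, pattern = "^batch_.*\\.csv$", full.names = TRUE)
if (!length(batches)) stop("no deposited batches found; run analysis/01_simulate_stream.R first")

message("reading ", length(batches), " batches ...")
concat <- do.call(rbind, lapply(sort(batches), utils::read.csv,
                                stringsAsFactors = FALSE,
                                colClasses = "character"))
all_path <- file.path("scratch", "stream_concat.csv")
utils::write.csv(concat, all_path, row.names = FALSE)
stream <- read_trials(all_path)

cfg <- design_config()
point1 <- cfg$analysis_points[1]
confirmatory <- filter_confirmatory(stream, analysis_point = point1)
counts <- pooled_success_counts(confirmatory)
message(sprintf("confirmatory set: %d erotic trials, %d successes (%.2f%%)",
                counts[["n"]], counts[["k"]], 100 * counts[["k"]] / counts[["n"]]))

look1 <- evaluate_look(confirmatory, 1L, cfg)
print(look1)

dir.create("results", showWarnings = FALSE)
jsonlite::write_json(list(
  look = 1, n = look1$n_trials, k = look1$k,
  ci = look1$ci[c("level", "lo", "hi", "estimate")],
  ci_verdict = look1$ci_verdict,
  bf01 = as.list(look1$bf01),
  bf_verdicts = as.list(look1$bf_verdicts),
  conjunction = look1$conjunction
), file.path("results", "look1_report.json"), auto_unbox = TRUE, digits = NA)

message("tracking the Bayes-factor trajectory ...")
traj <- bf_trajectory(confirmatory, cfg, step = 200L)
utils::write.csv(traj, file.path("results", "bf_trajectory.csv"), row.names = FALSE)

if (look1$conjunction == "continue") {
  message(interim_warning_banner(cfg$analysis_points[2]))
} else {
  message("stopping rule triggered at the first analysis point: ",
          sub("stop_", "", look1$conjunction))
}

# the full sequential run (errors if the stream cannot reach a later look)
outcome <- tryCatch(run_study(stream, cfg), error = function(e) {
  message("sequential run: ", conditionMessage(e)); NULL
})
if (!is.null(outcome)) print(outcome)

write_run_manifest(file.path("results", "confirmatory_manifest.json"),
                   command = "confirmatory_analysis",
                   config = list(analysis_point = point1),
                   inputs = all_path,
                   outputs = file.path("results",
                                       c("look1_report.json", "bf_trajectory.csv")))
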