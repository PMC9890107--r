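#!/usr/bin/env Rscript

# Step 3 — robustness re-analysis of the confirmatory counts.
#
# Two alternative views of the pooled erotic-trial counts from the
# confirmatory set: (1) the pair of one-sided exact binomial tests at
# alpha = 0.005 (reject "p >= 51%" -> support M0; else reject
# "p <= 50%" -> support M1), and (2) the conjugate replication-prior
# posterior Beta(829 + k, 733 + (n - k)) with its mode, 90% HDI and the
# ROPE [0, 0.506] mass decision.

suppressPackageStartupMessages(library(seqpsi))

report_path <- file.path("results", "look1_report.json")
if (!file.exists(report_path)) stop("run analysis/02_confirmatory_analysis.R first")
look1 <- jsonlite::read_json(report_path, simplifyVector = TRUE)
k <- look1$k; n <- look1$n

prop <- one_sided_proportion_tests(k, n)
message(sprintf("proportion tests: p(M0 side) = %.4g, p(M1 side) = %.4g -> %s",
                prop$p_le_sesoi, prop$p_gt_null, prop$verdict))

post <- posterior_update(k, n)
message(sprintf("posterior Beta(%d, %d): mode %.4f, 90%% HDI [%.4f, %.4f], %.1f%% in ROPE -> %s",
                post$post_a, post$post_b, post$mode, post$hdi_lo, post$hdi_hi,
                100 * post$mass_in_rope, post$verdict))

jsonlite::write_json(list(
  k = k, n = n,
  proportion_tests = prop,
  posterior = post[c("post_a", "post_b", "mode", "hdi_lo", "hdi_hi",
                     "mass_in_rope", "tail_above_rope", "verdict")]
), file.path("results", "robustness.json"), auto_unbox = TRUE, digits = NA)

write_run_manifest(file.path("results", "robustness_manifest.json"),
                   command = "robustness", inputs = report_path,
                   outputs = file.path("results", "robustness.json"))
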