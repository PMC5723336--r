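#!/usr/bin/env Rscript

# Step 3 — score the pipeline against the simulator's ground truth:
#   * percent-community recovery across carrier fractions 5/20/50%
#   * copy-number correction (2 copies -> uncorrected ~= 2x corrected)
#   * placement accuracy of error-free reads (>= 60 informative aa)
#   * outgroup filtering under 10% contamination
# Writes results/benchmarks.tsv.

suppressMessages(library(placeprof))

seed <- 42L
dir.create("results", showWarnings = FALSE)
rows <- list()

for (f in c(0.05, 0.2, 0.5)) {
  res <- benchmark_abundance_recovery(f, seed = seed, n_pairs = 900)
  env <- recovery_envelope(f, res$rpob_placed, res$gene_len, res$rpob_len)
  rows[[length(rows) + 1]] <- data.frame(
    benchmark = sprintf("percent_community_f%02.0f", f * 100),
    truth = 100 * f, estimate = res$percent,
    lower95 = env[1], upper95 = env[2], n = res$rpob_placed)
  message(sprintf(
    "carrier fraction %4.0f%%: estimated %5.2f%% (95%% envelope %.2f-%.2f, %d rpoB reads)",
    100 * f, res$percent, env[1], env[2], res$rpob_placed))
}

mc <- benchmark_copy_number(seed = seed, n_pairs = 1100)
rows[[length(rows) + 1]] <- data.frame(
  benchmark = "narG_uncorrected", truth = 100, estimate = mc$uncorrected,
  lower95 = NA, upper95 = NA, n = mc$rpob_placed)
rows[[length(rows) + 1]] <- data.frame(
  benchmark = "narG_corrected", truth = 50, estimate = mc$corrected,
  lower95 = NA, upper95 = NA, n = mc$rpob_placed)
message(sprintf("copy-number: uncorrected %.1f%% vs corrected %.1f%%",
                mc$uncorrected, mc$corrected))

pr <- benchmark_placement_recovery(seed = seed, n_pairs = 700)
rows[[length(rows) + 1]] <- data.frame(
  benchmark = "placement_recovery_rate", truth = NA,
  estimate = 100 * pr$rate, lower95 = NA, upper95 = NA, n = pr$n_scored)
message(sprintf("placement recovery: %.1f%% of %d queries on/adjacent to source leaf",
                100 * pr$rate, pr$n_scored))

og <- benchmark_outgroup_filter(seed = seed, n_pairs = 2500)
rows[[length(rows) + 1]] <- data.frame(
  benchmark = "outgroup_discard_rate", truth = NA,
  estimate = 100 * og$discard_rate, lower95 = NA, upper95 = NA,
  n = og$n_outgroup_placed)
message(sprintf("outgroup filter: %.1f%% of %d contaminant queries discarded",
                100 * og$discard_rate, og$n_outgroup_placed))

write_tsv(do.call(rbind, rows), "results/benchmarks.tsv")
message("wrote results/benchmarks.tsv")
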