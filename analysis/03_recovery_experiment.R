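#!/usr/bin/env Rscript

# Repeats the whole reconstruction on 20 independently seeded synthetic
# worlds and scores the recovered long-term trends against the planted
# generator values: sign, relative error, and coverage of the reported 95%
# confidence intervals. Writes the per-series scores and a summary table.
# Takes on the order of ten minutes on one CPU.

suppressPackageStartupMessages(library(riacarb))

dir.create("results", showWarnings = FALSE)

rec <- recovery_experiment(seeds = 1:20)
utils::write.csv(rec, "results/recovery_scores.csv", row.names = FALSE)

summ <- do.call(rbind, lapply(split(rec, rec$variable), function(sub) {
  data.frame(variable = sub$variable[1],
             n = nrow(sub),
             sign_correct_pct = 100 * mean(sub$sign_correct),
             ci_coverage_pct = 100 * mean(sub$covered),
             mean_rel_error_pct = 100 * mean((sub$B - sub$planted) /
                                               abs(sub$planted)))
}))
utils::write.csv(summ, "results/recovery_summary.csv", row.names = FALSE)
message("per-variable recovery over 20 worlds x 18 strata:")
print(summ, row.names = FALSE)

message(paste(
  "\nNote: reported CIs come from ordinary least squares on the",
  "network-reconstructed weekly series; they do not include the networks'",
  "own reconstruction error, so their coverage of the planted trend is far",
  "below nominal even though signs and magnitudes are recovered well.",
  "See the methods vignette for the full discussion."))
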