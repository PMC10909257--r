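#!/usr/bin/env Rscript
# Stage 6 -- analytical greenness.
#
# Scores the methanol-based spectrophotometric procedure and the water-based
# reported comparator on the Eco-scale penalty-point system, and aggregates
# the 12-principle AGREE-style profile (per-principle scores are a synthetic
# reconstruction; only the aggregation rule is exercised).

suppressPackageStartupMessages(library(quatspec))

proposed <- eco_scale(eco_items_proposed())
reported <- eco_scale(eco_items_reported())
agree <- agree_score(agree_scores_synthetic())

cat("Proposed procedure:\n"); print(proposed)
cat("\nReported comparator:\n"); print(reported)
cat(sprintf("\nAGREE-style overall score: %.2f\n", agree$overall))

out <- list(
  proposed = list(score = proposed$score, total_pp = proposed$total_pp,
                  verdict = proposed$verdict),
  reported = list(score = reported$score, total_pp = reported$total_pp,
                  verdict = reported$verdict),
  agree = list(overall = agree$overall,
               principle_scores = as.list(agree$principle_scores)))
dir.create("results/run", recursive = TRUE, showWarnings = FALSE)
jsonlite::write_json(out, "results/run/greenness.json",
                     auto_unbox = TRUE, digits = NA)
cat("wrote results/run/greenness.json\n")
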