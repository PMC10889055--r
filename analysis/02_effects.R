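#!/usr/bin/env Rscript
# Score every candidate variant across its genetic contexts against the
# n = 999 empirical background null, and filter at the standard operating
# point (|log-odds change| >= 1, e <= 0.05). Writes the effects table,
# flagged rows, context summaries and the background null under
# results/effects/.

library(caism)

spec <- default_scenario(seed = 7)
res <- run_all(spec, file.path("results", "effects"))

cat("Scored", nrow(res$effects), "records:",
    length(spec$candidates), "candidates x 8 contexts x",
    length(spec$features), "features\n\n")

cat("Variant/feature pairs passing |log-odds change| >= 1 and e <= 0.05:\n")
print(res$report$summary[, c("variant_id", "feature", "min_loc", "max_loc",
                             "range", "label")], row.names = FALSE)

key <- spec$answer_key
hit <- unique(res$report$flagged$variant_id)
cat("\nFlagged variants:", paste(sort(hit), collapse = ", "), "\n")
cat("Planted variants:",
    paste(sort(key$true_effects$variant_id), collapse = ", "), "\n")
cat(if (setequal(hit, key$true_effects$variant_id))
      "All planted effects recovered, no false positives."
    else "MISMATCH against the planted answer key.", "\n")
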