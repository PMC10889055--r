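#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a genome with planted motif effects,
# candidate/neighbour variants, phased haplotypes with a high-LD pair, and a
# case/control cohort with a planted protective interaction. All files are
# plain text under results/sim/.

library(caism)

spec <- default_scenario(seed = 7)
dir <- file.path("results", "sim")
write_scenario(spec, dir)

cat("Scenario (seed", spec$seed, ") written to", dir, "\n")
print(spec)
cat("\nPlanted truth:\n")
print(spec$answer_key$true_effects)
cat("\nCooperative pair:", spec$answer_key$context$center, "x",
    spec$answer_key$context$partner, "on", spec$answer_key$context$feature,
    "- logit margin", spec$answer_key$context$margin, "\n")
cat("LD pair:", spec$answer_key$ld$anchor, "/", spec$answer_key$ld$partner,
    "target r2", spec$answer_key$ld$target_r2, "\n")
cat("Epistatic pair:", spec$answer_key$epistasis$a, "/",
    spec$answer_key$epistasis$b, "interaction OR",
    spec$answer_key$epistasis$or_interaction, "\n")
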