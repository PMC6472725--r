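#!/usr/bin/env Rscript
# Lambda-weighted contrast analysis: do the per-sector outcome patterns
# follow the terrain-inclination pattern? Weights are the z-scored
# inclinations of sectors 4-11; per subject the sector values collapse to
# one contrast score, tested one-tailed against zero at alpha = 0.01.

suppressPackageStartupMessages(library(pedalphase))

measures <- read_measures_table("results/measures.csv")
profile <- read_terrain_profile("scratch/synthetic_study/terrain.csv",
                                analysis_ids = 4:11)
config <- run_config()

tab <- run_contrast_table(measures, profile, config)
dir.create("results", showWarnings = FALSE)
write_contrast_table(tab, "results/contrast.csv")

print(tab, row.names = FALSE, digits = 4)

sig <- function(cond, var) tab$significant[tab$condition == cond &
                                             tab$variable == var]
cat("\nWith fixed gearing (NO_SHIFT) the attractor measures",
    "LR, Mc, ML1 and heart rate",
    if (all(sapply(c("LR", "Mc", "ML1", "HR"), sig, cond = "NO_SHIFT")))
      "all track the inclination pattern (p < 0.01)."
    else "do NOT all reach significance — inspect results/contrast.csv.",
    "\n")
cat("With free gearing (SHIFT) the attractor measures",
    if (!any(sapply(c("LR", "Mc", "ML1"), sig, cond = "SHIFT")))
      "decouple from terrain (all p >= 0.01),"
    else "unexpectedly remain coupled,",
    "and RevTimeCV is terrain-independent in both sessions:",
    !sig("SHIFT", "RevTimeCV") && !sig("NO_SHIFT", "RevTimeCV"), "\n")
cat("\nwritten to results/contrast.csv\n")
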