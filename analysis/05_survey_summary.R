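#!/usr/bin/env Rscript
# Step 5: quantile summary of a literature-survey table of spectroscopic
# lignin-prediction case studies (species count, extraction sample mass,
# validation/calibration ratio, and accuracy measures). The shipped table
# is SYNTHETIC — a stand-in with the shape and missingness pattern of a
# real survey, for exercising the summary; swap in a real survey CSV with
# the same columns to summarize actual studies.

suppressPackageStartupMessages(library(rootlignin))
dir.create("results", showWarnings = FALSE)

path <- system.file("extdata", "survey_synthetic.csv", package = "rootlignin")
survey <- read.csv(path)
cat(sprintf("survey records: %d case studies\n", nrow(survey)))

summ <- summarize_survey(survey)
print(round(summ, 2))
cat("non-missing records per column:\n")
print(attr(summ, "n"))

out <- cbind(stat = rownames(summ), round(summ, 3))
write.csv(out, "results/survey_summary.csv", row.names = FALSE)
cat("wrote results/survey_summary.csv\n")
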