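#!/usr/bin/env Rscript
# Step 3 -- summarise Pearson residuals into riSD.
#
# For every participant with at least two observations, riSD is the
# within-person standard deviation of their residuals: the study's
# proxy for intra-individual variability in contact behaviour.

suppressMessages(library(contactiiv))

tab <- read_survey_csv("results/survey.csv")
res <- read.csv("results/residuals.csv")
df <- merge(tab, res[c("participant_id", "wave_index", "r")],
            by = c("participant_id", "wave_index"))

rs <- risd(df, min_obs = 2,
           carry = c("age_group", "sex", "household_size", "occupation"))
write.csv(rs, "results/risd.csv", row.names = FALSE)

cat("riSD units:", nrow(rs), "participants (",
    attr(rs, "exclusions")[["below_min_obs"]],
    "excluded with < 2 observations)\n")
cat("riSD: mean", round(mean(rs$risd), 2),
    "| median", round(median(rs$risd), 2),
    "| IQR", paste(round(quantile(rs$risd, c(0.25, 0.75)), 2),
                   collapse = "-"),
    "| max", round(max(rs$risd), 2), "\n")
cat("wrote results/risd.csv\n")
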