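#!/usr/bin/env Rscript
# Step 1 -- generate the synthetic contact-survey panel.
#
# 300 participants over 24 waves starting 2020-04-01, so the panel
# spans the vaccination rollout (late December 2020) and several
# strong/weak stringency phases. Writes the survey table and a short
# structural summary.

suppressMessages(library(contactiiv))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(n_participants = 300, n_waves = 24, seed = 20260927)
tab <- simulate_population(cfg)
write_survey_csv(tab, "results/survey.csv")

n_per <- table(tab$participant_id)
cat("panel:", length(n_per), "participants,", nrow(tab), "observations,",
    cfg$n_waves, "waves\n")
cat("observations per participant: mean", round(mean(n_per), 1),
    "| single-wave participants:", sum(n_per == 1), "\n")
cat("non-household contacts: mean", round(mean(tab$y), 2),
    "| median", median(tab$y),
    "| share zero", round(mean(tab$y == 0), 2),
    "| max", max(tab$y), "\n")
cat("stringency index range:", round(min(tab$SI), 1), "-",
    round(max(tab$SI), 1),
    "| share strong (SI >= 50):", round(mean(tab$SI >= 50), 2), "\n")
cat("participants with a first dose in-study:",
    length(unique(tab$participant_id[!is.na(tab$first_dose_date)])), "\n")
cat("wrote results/survey.csv\n")
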