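#!/usr/bin/env Rscript
# Step 4 -- the three mean-ratio regressions.
#
# riSD is modelled with weighted Gamma log-link regressions
# (weights = observations behind each riSD):
#   1. sociodemographic differences (age, sex, household size,
#      occupation),
#   2. pre vs post first-vaccination window (-100..0 vs 1..100 days),
#   3. weak vs strong policy stringency (SI < 50 vs >= 50),
# the paired designs restricted to participants with at least two
# observations on each side.

suppressMessages(library(contactiiv))

tab <- read_survey_csv("results/survey.csv")
res <- read.csv("results/residuals.csv")
df <- merge(tab, res[c("participant_id", "wave_index", "r")],
            by = c("participant_id", "wave_index"))
covs <- c("age_group", "sex", "household_size", "occupation")

# 1: sociodemographic predictors of riSD
rs <- risd(df, carry = covs)
fit1 <- fit_gamma_glm(rs, covs)
cat("\n-- sociodemographic analysis (", fit1$n_units, "participants ) --\n")
print(fit1)
write.csv(mean_ratio_table(fit1), "results/mr_sociodemographic.csv",
          row.names = FALSE)

run_window <- function(kind) {
  w <- if (kind == "vaccination") vaccination_windows(df)
       else stringency_windows(df)
  obs <- w$observations
  obs <- obs[obs$participant_id %in% w$eligible, ]
  rs <- risd(obs, by = "participant_window", carry = covs)
  rs$window_label <- factor(rs$window_label,
    levels = if (kind == "vaccination") c("pre_vax", "post_vax")
             else c("strong_SI", "weak_SI"))
  fit <- fit_gamma_glm(rs, c(covs, "window_label"))
  cat("\n--", kind, "analysis (", length(w$eligible),
      "eligible participants ) --\n")
  print(fit)
  write.csv(mean_ratio_table(fit),
            sprintf("results/mr_%s.csv", kind), row.names = FALSE)
  fit
}
fit2 <- run_window("vaccination")
fit3 <- run_window("stringency")
cat("\nwrote results/mr_{sociodemographic,vaccination,stringency}.csv\n")
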