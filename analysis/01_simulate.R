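#!/usr/bin/env Rscript
# Stage 1 — simulate the study data.
#
# Generates the default synthetic multi-country ageing survey: 6 countries
# (two per income tier) x 2000 persons aged 55+, household incomes lognormal
# around tier medians, a two-stage stratum/cluster design, binary ADL/IADL/
# mobility outcomes with a pro-poor rank-linear gradient, and 10% MCAR
# missingness in the explanatory variables.  Writes the microdata, the
# country macro table and the reference age structure under results/data/.

suppressPackageStartupMessages(library(rifineq))

seed <- 20260926L %% 1000L   # fixed study seed
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(seed = seed)
study <- generate_survey(cfg, missingness = TRUE)

write_microdata(study$microdata, "results/data/microdata.csv")
write.csv(study$macro, "results/data/macro.csv", row.names = FALSE)
write.csv(study$reference_ages, "results/data/reference_ages.csv",
          row.names = FALSE)

micro <- study$microdata
message(sprintf("simulated %d persons in %d countries (%d households)",
                nrow(micro), length(unique(micro$country_code)),
                length(unique(micro$household_id))))
for (dom in c("adl", "iadl", "mobility")) {
  message(sprintf("  crude %s prevalence: %s%%", dom,
                  format_percent(100 * mean(micro[[dom]]))))
}
message(sprintf("  missing explanatory cells: %s%% of education",
                format_percent(100 * mean(is.na(micro$education)))))
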