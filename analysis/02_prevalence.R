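#!/usr/bin/env Rscript
# Stage 2 — design-weighted, age-post-stratified prevalence.
#
# Post-stratifies the sampling weights to the reference age composition
# within each country, then tabulates disability prevalence with 95% CIs by
# country and by within-country income quintile, and the quintile
# percentage difference ((Q1 - Q5)/Q1 x 100).  Expects stage 1 outputs.

suppressPackageStartupMessages(library(rifineq))

micro <- read_microdata("results/data/microdata.csv")
ref <- read.csv("results/data/reference_ages.csv")

prev <- prevalence_table(micro, ref)
prev_q <- prevalence_table(micro, ref, by_quintile = TRUE)

pd <- do.call(rbind, lapply(split(prev_q, prev_q[c("domain", "country_code")],
                                  drop = TRUE), function(g) {
  data.frame(domain = g$domain[1], country_code = g$country_code[1],
             pct_difference = percentage_difference(
               g$prevalence[g$quintile == 1], g$prevalence[g$quintile == 5]))
}))

write_table(prev, "results/prevalence.tsv")
write_table(prev_q, "results/quintile_prevalence.tsv")
write_table(pd, "results/percentage_difference.tsv")

for (dom in unique(prev$domain)) {
  p <- prev[prev$domain == dom, ]
  message(sprintf("%s prevalence across countries: %s%% to %s%%", dom,
                  format_percent(min(p$prevalence)),
                  format_percent(max(p$prevalence))))
}
message("percentage difference (poorest vs richest quintile), ADL by country: ",
        paste(format_percent(pd$pct_difference[pd$domain == "adl"]),
              collapse = ", "), "%")
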