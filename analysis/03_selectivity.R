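#!/usr/bin/env Rscript
# Na+/Cl- permeability ratios and selectivity classes per protomer and
# per voltage sign, with protomer-weighted (count-pooled) ratios.
#
# Writes: results/selectivity.tsv, results/selectivity_summary.tsv

source("analysis/00_cohort.R")

cohort <- build_cohort()
records <- lapply(cohort, function(p) {
  ev <- permeation_events(segment_visits(p$frames))
  conductance_record(p$frames, ev)
})

tab <- selectivity_table(records, min_events = 5)
write_tsv(tab, "selectivity.tsv")

summ <- do.call(rbind, lapply(split(tab, tab$voltage_sign), function(g) {
  w <- weighted_ratio(g$G_Na, g$G_Cl)
  data.frame(voltage_sign = g$voltage_sign[1],
             n_protomers = nrow(g),
             n_classified = sum(g$class != "insufficient"),
             G_Na_total = sum(g$G_Na), G_Cl_total = sum(g$G_Cl),
             ratio_pooled = w$pooled, ratio_mean = w$mean_ratio)
}))
write_tsv(summ, "selectivity_summary.tsv")

for (i in seq_len(nrow(summ)))
  message(sprintf(
    "V %s: pooled P_Na/P_Cl = %.2f over %d classified protomers",
    summ$voltage_sign[i], summ$ratio_pooled[i], summ$n_classified[i]))
message("class counts: ",
        paste(sprintf("%s=%d", names(table(tab$class)), table(tab$class)),
              collapse = " "))
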