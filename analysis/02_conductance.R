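#!/usr/bin/env Rscript
# Detect permeation events and compute per-protomer conductance
# statistics: event counts per species, time to first event, mean
# conductance G_m, median instantaneous conductance G_i, and the
# conductive-protomer fraction over a threshold sweep.
#
# Writes: results/conductance.tsv, results/conductive_fraction.tsv

source("analysis/00_cohort.R")

cohort <- build_cohort()

records <- lapply(cohort, function(p) {
  ev <- permeation_events(segment_visits(p$frames))
  conductance_record(p$frames, ev)
})

tab <- do.call(rbind, lapply(records, function(r) {
  data.frame(protomer_id = r$protomer_id, voltage_mV = r$voltage,
             N_Na = unname(r$N_p["NA"]), N_Cl = unname(r$N_p["CL"]),
             t1_ns = r$t1 / 1e3,
             G_m_pS = r$G_m, G_i_median_pS = r$G_i_median)
}))
write_tsv(tab, "conductance.tsv")

gm <- tab$G_m_pS
s <- summarize_values(gm[!is.na(gm)])
message(sprintf(
  "G_m over %d conducting protomers: median %.2f pS (IQR %.2f-%.2f)",
  s$n, s$median, s$q1, s$q3))
gi <- tab$G_i_median_pS
message(sprintf("median instantaneous conductance, cohort median: %.2f pS",
                median(gi, na.rm = TRUE)))

sweep <- conductive_fraction(gm, thresholds = c(0.5, 1, 2, 5, 10, 20, 50))
write_tsv(data.frame(threshold_pS = as.numeric(names(sweep)),
                     fraction_conductive = as.numeric(sweep)),
          "conductive_fraction.tsv")
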