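#!/usr/bin/env Rscript
# Headgroup-blockage geometry: in-plane distance between the phosphate
# moiety and the ion permeation pathway at the cavity sodium site,
# compared between the open (permeating) and closed (blocked) pore
# states with the one-sided Mann-Whitney test.
#
# Writes: results/blockage_distances.tsv, results/blockage_test.tsv

source("analysis/00_cohort.R")

site <- default_sites("nhTMEM16")$Na_v
n_per_state <- 15L

open <- lapply(seq_len(n_per_state), function(i)
  generate_blockage_protomer(COHORT_SEED + 100 + i, site, "open",
                             distance = 6, noise_sd = 0.5))
closed <- lapply(seq_len(n_per_state), function(i)
  generate_blockage_protomer(COHORT_SEED + 200 + i, site, "closed",
                             distance = 4, noise_sd = 0.5))
fso <- lapply(open, `[[`, "frames")
fsc <- lapply(closed, `[[`, "frames")
for (i in seq_along(fso)) fso[[i]]$protomer_id <- sprintf("open%02d", i)
for (i in seq_along(fsc)) fsc[[i]]$protomer_id <- sprintf("closed%02d", i)
vo <- lapply(fso, segment_visits)
vc <- lapply(fsc, segment_visits)

pathway <- mean_pathway_point(fso, vo, site)
message(sprintf("permeation pathway at %s: (%.2f, %.2f) A from %d points",
                site$name, pathway$x, pathway$y, pathway$n_points))

d_open <- blockage_distances(fso, vo, site, "LIPID_P", "efflux",
                             "permeating", pathway = pathway)
d_closed <- blockage_distances(fsc, vc, site, "LIPID_P", "efflux",
                               "blocked", pathway = pathway)
d_open$state <- "open"; d_closed$state <- "closed"
write_tsv(rbind(d_open, d_closed), "blockage_distances.tsv")

mw <- mann_whitney_one_sided(d_open$mean_distance, d_closed$mean_distance,
                             "greater")
so <- summarize_values(d_open$mean_distance)
sc <- summarize_values(d_closed$mean_distance)
write_tsv(data.frame(
  site = site$name, moiety = "LIPID_P", direction = "efflux",
  n_open = mw$n1, n_closed = mw$n2,
  median_open_A = so$median, median_closed_A = sc$median,
  U = mw$U, p_one_sided = mw$p_value, method = mw$method),
  "blockage_test.tsv")
message(sprintf(
  "P-to-pathway distance: open median %.2f A vs closed %.2f A, one-sided Mann-Whitney p = %.2g",
  so$median, sc$median, mw$p_value))
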